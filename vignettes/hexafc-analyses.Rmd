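---
title: "Quantifying Fc-receptor hinge geometry, glycan dynamics, SPR kinetics and glycan masses with glycofc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Fc-receptor hinge geometry, glycan dynamics, SPR kinetics and glycan masses with glycofc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofc)
library(dplyr)
```

glycofc collects, in one tidyverse-shaped package, the desk-scale
quantitative analyses that recur in structural work on engineered
multimeric IgG1 Fc ("hexa-Fc") and its receptors and lectins: the D1–D2
hinge angle of Fc-gamma-receptor-like ectodomains, a two-state contact
classifier for the N-glycan conformations seen in molecular-dynamics
trajectories of glycosylated Fc, a geometric accessibility test for
lectin engagement, 1:1 Langmuir SPR kinetics (simulation and global
fitting), and permethylated N-glycan mass computation for MALDI-TOF
annotation. Every analysis operates on tidy tables and every input can be
generated synthetically, so the full pipeline is testable without
downloads or cluster-scale simulation.

## Structures and trajectories as tidy tables

`read_pdb()` parses fixed-column PDB (through bio3d) into a tibble with
one row per atom per frame; `MODEL` blocks become frames, `HETATM` glycan
residues are first-class, and alternate locations resolve to the
highest-occupancy conformer (ties to the first listed, so parsing is
deterministic). Residue numbers are author numbering exactly as printed
in the file, because hinge anchors and glycan sites are conventionally
cited in crystal-structure numbering. Only PDB-format (multi-model)
trajectories are supported; binary trajectory formats would buy nothing
at the problem sizes this package targets. Frames must share one atom
topology — mismatched `MODEL` blocks are rejected outright rather than
silently aligned.

## The D1–D2 hinge angle

Fc-gamma receptors present two immunoglobulin-like ectodomains whose
relative disposition — the hinge angle — separates the sharply bent
high-affinity receptor (~35° in the Fc-gamma-RI crystal structure, via
the Ile96/Gly103/Ser110 triplet) from the more open low-affinity
receptors (>50°). `hinge_angle()` measures the angle at a vertex anchor
between vectors to one anchor in each domain:

```{r hinge}
s <- make_hinge_structure(angle_deg = 50, seed = 7)
hinge_angle(s$structure, s$hinge)
```

Which atoms subtend the angle is not standardised; we default to the
C-alpha atoms of the three named residues (the usual backbone-level
convention) and leave `atom_name` overridable in `hinge_definition()`.
The statistic is exactly invariant under rigid-body motion and symmetric
in the outer anchors; both properties are enforced by tests at 1e-6
degrees over random transforms.

## Contacts and the two-state glycan classifier

The Asn297 N-glycan of an Fc heavy chain samples two configurations in
simulations of glycosylated Fc: one with the chitobiose core, the
beta-mannose and the alpha1–6 arm all packed against the C-gamma-2
domain, and a looser one in which only the chitobiose core stays close.
The discriminating statistic is a contact count: the number of
C-gamma-2 residues with at least one heavy atom within 3 Å (roughly
hydrogen-bonding distance, which is conventionally quoted between heavy
atoms — hence contacts always exclude H/D) of glycan residues 2–6. A
frame with **two or fewer** such residues is labelled *loose*, otherwise
*bound*.

Decisions worth stating once:

* Distance comparison is inclusive (`d <= cutoff`) so boundary behaviour
  is deterministic.
* Glycan indices 1..7 follow the Man5GlcNAc2 layout (two core GlcNAcs,
  beta-mannose, alpha1–3 mannose, alpha1–6 mannose, two terminal
  mannoses of the alpha1–6 arm). The probe window "residues 2 through 6"
  defaults to starting at the second core GlcNAc; whether such a window
  should instead start at the beta-mannose is a judgement call, so
  `probe_indices` is a parameter (`3:6` selects the alternative), with
  `2:6` as the documented default.
* The reference selection defaults to the C-gamma-2 residues of the same
  heavy chain the glycan is attached to; cross-chain contacts are
  excluded unless the caller widens the selection.
* No periodic-boundary imaging is attempted; frames are assumed whole,
  and any interatomic distance above 500 Å raises a warning.

```{r classify}
g <- make_glycan_state_trajectory(n_frames = 100,
                                  n_loose = c(U = 3, V = 34), seed = 1)
g$trajectory |>
  classify_glycan_states(g$topologies, g$spec) |>
  state_fractions()
```

The defaults of `make_glycan_state_trajectory()` emulate the statistical
structure reported for a ~150 ns glycosylated-Fc trajectory: two glycan
chains, one almost permanently bound (loose ~3.3% of frames), the other
loose ~34.5% of the time. A single published run gives no run-to-run
variance, so those fractions are context for the generator's defaults,
not quantities the package claims to reproduce; what the tests do verify
is that classification agrees with the generator's ground truth on
every designed frame, and recovers sampled fractions to within binomial
error (3 standard errors at 2000 frames). The toy frames are C-alpha /
single-atom pseudo-residues on a grid — they emulate contact counts, not
force-field energetics, water, or realistic glycan geometry, so passing
tests demonstrate correctness of the *operators*, not realism of any
trajectory.

## Is a buried mannose reachable by a lectin?

The entrance to the Fc cavity that houses the glycans is roughly
elliptical, about 2 nm × 3.5 nm, while each carbohydrate-recognition
domain (CRD) of a DC-SIGN tetramer is approximately a 3 nm sphere. Those
numbers make accessibility a pure geometry question.
`accessibility_check()` models the CRD as a probe sphere whose centre
must stay on the outside half-space of the entrance plane and project
into the entrance ellipse shrunk by the probe radius along each
semi-axis (the centre positions from which the sphere fits the opening).
Over that convex set the minimal probe-surface-to-target distance
(`clearance`) has a closed form: depth and in-plane point-to-ellipse
distance combine by Pythagoras. We report both `clearance` and
`margin = contact_distance − clearance`; the target is accessible when
the margin is non-negative (a 1e-9 nm tolerance absorbs floating-point
noise on the boundary). With the default 1.5 nm probe against a 1.0 nm
semi-minor axis the shrunk ellipse is empty, and the check reports the
probe as geometrically blocked rather than erroring — which is precisely
the published argument for why deeply buried mannoses cannot engage a
CRD until the glycan swings to the cavity entrance. The entrance frame
(origin, normal, major axis) is user-supplied: the dimensions are
published but no algorithmic cavity detector is, and guessing one would
be false precision.

## 1:1 Langmuir SPR kinetics

Binding of an analyte at concentration \(C\) to a sensor surface follows
\[ dR/dt = k_{on} C (R_{max} - R) - k_{off} R, \qquad K_D = k_{off}/k_{on}, \]
whose closed form we simulate per concentration: association
\(R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})\) with
\(R_{eq} = R_{max} k_{on} C / (k_{on} C + k_{off})\), then exponential
decay at rate \(k_{off}\) after the buffer switch (default 300 s). The
analytic path is cross-checked in the tests against independent ODE
integration (plain Euler and an adaptive integrator) to 0.1%.

`fit_langmuir()` fits \(k_{on}, k_{off}, R_{max}\) **globally** across
all concentrations — multi-channel data recorded on one surface shares
one parameter set; per-curve mode exists for diagnostics. The optimiser
is Levenberg–Marquardt (minpack.lm) on log-transformed parameters, which
keeps rates positive without constraints; tolerances are 1e-10 on the
cost with a 10,000-evaluation cap, and the starting point is derived
from curve features (dissociation log-slope for \(k_{off}\), the
response plateau for \(R_{max}\), the association half-time for
\(k_{on}\)). \(K_D\) is always derived as fitted \(k_{off}/k_{on}\),
never fitted as a free parameter. Non-convergence is reported as a
flagged result, not an exception.

```{r spr}
fx <- make_sensorgrams(noise_sd = 1, seed = 42)   # 1% of Rmax noise
fit <- fit_langmuir(fx$curves)
tidy(fit)
```

The defaults of `make_sensorgrams()` are the apparent hexa-Fc/DC-SIGN
constants (\(k_{on} = 6.68\times10^2\) M\(^{-1}\)s\(^{-1}\),
\(k_{off} = 8.39\times10^{-4}\) s\(^{-1}\), so \(K_D = 1.26\) µM) with a
six-step doubling dilution from \(16 K_D\) — the published figures show
doubling dilutions but not the numeric series, so top concentration and
dilution count are parameters rather than asserted constants. Avidity
(the reason a hexamer out-binds a dimer) is represented only through
these apparent constants; mass-transport limitation, bulk
refractive-index jumps, drift and multivalent models are deliberately
out of scope, and synthetic noise is i.i.d. Gaussian. Round-trip
recovery is 0.1% noiseless and within 10% at 1% \(R_{max}\) noise across
20 seeds. One published triplet (SIGNR1/gp120: \(K_D\) 3.91 nM with
\(k_{off}/k_{on} \approx 3.42\) nM) is internally inconsistent;
`kd_from_rates()` reports what the rates imply and the discrepancy is
documented rather than reconciled.

## Permethylated N-glycan masses

Permethylation replaces every exchangeable hydrogen with a methyl group
before MALDI-TOF MS, and ions fly as \([M+Na]^+\). The mass of a
composition is

\[ m/z = \sum_i n_i \, m_i + (\mathrm{H_2O} + 2\,\mathrm{CH_2}) + m_{Na}, \]

with per-residue permethylated masses derived from elemental formulas
(native in-chain residue plus one CH\(_2\) per methylation site: 3 for
Hex and HexNAc, 2 for deoxyhexose, 5 for NeuAc including the carboxyl
methyl ester). The frozen table in `permethylated_mass_table()` is
asserted against the elemental route (`mass_table_from_elements()`) to
0.001 Da in the tests — the table is a cache, never an authority.
Monoisotopic (not average) masses are used throughout because reflectron
spectra are labelled with monoisotopic integers; integer comparison
rounds half away from zero.

```{r mass}
permethylated_mz(glycan_composition(hexnac = 4, hex = 5, dhex = 1))
annotate_peaks(c(2244.1, 2693.3)) |>
  filter(assigned) |>
  group_by(peak_mz) |>
  slice_min(abs(error), n = 1)
```

`enumerate_compositions()` inverts the mass by exhaustive search within
count bounds (defaults HexNAc 2–8, Hex 3–12, dHex 0–3, NeuAc 0–4 —
NeuGc and sulfated/phosphorylated classes are excluded because they are
not reported for these samples). The default match tolerance is 0.5 Da,
matching integer peak labels. Annotation reports *all* in-tolerance
compositions ranked by error — deliberately so: an ion near m/z 3504,
for example, admits a sialylated composition
(HexNAc6 Hex7 dHex1 NeuAc1) whose interpretation belongs to the analyst,
not the software. `fucose_isomer_masses()` records the one piece of
MS\(^1\) bookkeeping that matters for fucose placement: core and
antennal fucose are isobaric, so MS\(^1\) annotation alone can never
distinguish a core-fucosylated structure from a Lewis-X-like antenna —
that call needs MS/MS.

## Synthetic data as first-class fixtures

Every generator (`make_hinge_structure()`,
`make_glycan_state_trajectory()`, `make_sensorgrams()`,
`make_peak_list()`) emits its ground truth alongside the fixture, draws
all randomness from one seed via an isolated RNG (the caller's RNG
stream is untouched), and offers a deterministic design mode (exact
counts) next to the stochastic sampling mode. Tests default to design
mode so that expected values are exact. Structures are C-alpha-only
pseudo-proteins placed at a random rigid orientation: the analysis
operators, not structural realism, are the testable surface.

## Problem sizes and limitations

The shipped tests run at desk scale: trajectories of 100–2000 frames of
~23 atoms, sensorgram series of six concentrations at 1 s sampling over
600 s, 20-seed noise replicates, and composition searches over ~1400
candidates. These sizes were chosen as the smallest at which the
statistical assertions (binomial error bands, 10% noisy-recovery bounds)
are meaningful. What the package does *not* do: run or post-process
binary MD trajectories, model multivalent SPR binding, predict MS/MS
fragments, detect the Fc cavity automatically, or validate structures.
The published MD-scale numbers themselves (~50° equilibrated hinge for
the B-cell receptor FcRL5 homology model; 96.7%/34.5% state fractions)
require 100+ ns of atomistic simulation and are therefore treated as
the conditions the generators emulate, not as values the package
reproduces.
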