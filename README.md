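# glycofc

Desk-scale quantitative analyses for structural studies of multimeric
IgG1 Fc ("hexa-Fc") and its receptors and lectins, as a tidyverse-native
R package. It is written for structural immunologists and glycobiologists
who need the *numbers* behind such studies — hinge angles, glycan-state
fractions, kinetic constants, glycan masses — reproducibly, on tidy
tables, without cluster-scale simulation or instrument software.

Five analysis surfaces:

* **Structure I/O** — multi-model PDB files in and out as tidy atom
  tables (one row per atom per frame), with deterministic altloc
  resolution and declarative atom selections.
* **Hinge geometry** — the D1–D2 interdomain hinge angle of
  Fc-gamma-receptor-like ectodomains: the angle at a vertex residue
  between vectors to one anchor residue per domain (Cα by convention),
  per model or per trajectory frame, plus generic 3 Å heavy-atom contact
  counting with an exhaustive-oracle guarantee.
* **Glycan dynamics** — the two-state classifier for Asn297-glycan
  configurations: a frame is *loose* when ≤ 2 Cγ2-domain residues lie
  within 3 Å of glycan residues 2–6, *bound* otherwise; per-chain
  trajectory state fractions; and a closed-form geometric test of
  whether a spherical lectin carbohydrate-recognition domain (default
  3 nm diameter) can reach a mannose through an elliptical cavity
  entrance (default 2 nm × 3.5 nm).
* **SPR kinetics** — simulation and global Levenberg–Marquardt fitting
  of 1:1 Langmuir sensorgrams, `dR/dt = kon·C·(Rmax − R) − koff·R`, with
  `KD = koff/kon` always derived from the fitted rates.
* **Glycan masses** — permethylated, sodiated monoisotopic m/z of
  N-glycan compositions (`m/z = Σ nᵢ·mᵢ + (H₂O + 2 CH₂) + m(Na)`),
  composition enumeration within bounds, and MALDI-TOF peak-list
  annotation; the residue mass table is validated against an elemental
  oracle.

Seeded synthetic-data generators (`make_hinge_structure()`,
`make_glycan_state_trajectory()`, `make_sensorgrams()`,
`make_peak_list()`) emit fixtures *with ground truth*, so every analysis
has an end-to-end round-trip test.

## Worked example

```r
library(glycofc)
library(dplyr)

# A two-domain structure built at a 50 degree hinge, recovered exactly
s <- make_hinge_structure(angle_deg = 50, seed = 7)
hinge_angle(s$structure, s$hinge)
#> [1] 50

# Two glycan chains designed loose in 3 and 34 of 100 frames
g <- make_glycan_state_trajectory(n_frames = 100,
                                  n_loose = c(U = 3, V = 34), seed = 1)
g$trajectory |>
  classify_glycan_states(g$topologies, g$spec) |>
  state_fractions()
#> # A tibble: 2 × 4
#>   chain n_frames f_bound f_loose
#>   <chr>    <int>   <dbl>   <dbl>
#> 1 U          100    0.97    0.03
#> 2 V          100    0.66    0.34

# Simulate noisy doubling-dilution sensorgrams at the apparent
# hexa-Fc/DC-SIGN constants and refit them globally
fx <- make_sensorgrams(noise_sd = 1, seed = 42)   # kon 668, koff 8.39e-4
fit <- fit_langmuir(fx$curves)
fit
#> Global 1:1 Langmuir fit (6 curves, 3606 points)
#>   kon  = 667.2 M^-1 s^-1
#>   koff = 0.0008373 s^-1
#>   Rmax = 99.98 RU
#>   KD   = 1.255e-06 M (koff/kon)
#>   converged: TRUE

kd_from_rates(6.68e2, 8.39e-4)   # the printed rates imply KD = 1.26 uM
#> [1] 1.255988e-06

# Permethylated [M+Na]+ mass of the core-fucosylated biantennary glycan
permethylated_mz(glycan_composition(hexnac = 4, hex = 5, dhex = 1))
#> [1] 2244.125

# Annotate a MALDI peak list (top-ranked match per peak)
annotate_peaks(c(2244.1, 2693.3)) |>
  filter(assigned) |>
  group_by(peak_mz) |>
  slice_min(abs(error), n = 1)
#> # A tibble: 2 × 9
#>   peak_mz intensity assigned HexNAc   Hex  dHex NeuAc mz_calc  error
#>     <dbl>     <dbl> <lgl>     <int> <int> <int> <int>   <dbl>  <dbl>
#> 1   2244.        NA TRUE          4     5     1     0   2244. 0.0250
#> 2   2693.        NA TRUE          5     6     1     0   2693. 0.0511
```

The fitted rates land within a fraction of a percent of the generating
constants at this noise level (1% of Rmax); the recovered state
fractions equal the design exactly because the generator realises the
contact counts deterministically; and the two annotated peaks are the
fucosylated bi- and triantennary compositions their integer labels
suggest.

`tidy()` / `glance()` summarise fits broom-style, and
`plot_sensorgrams()`, `autoplot()` on a fit, `plot_angle_series()` and
`plot_state_fractions()` give ggplot views of each result type. The
methods vignette (`vignettes/hexafc-analyses.Rmd`) documents the models,
parameter conventions and design decisions in detail.

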