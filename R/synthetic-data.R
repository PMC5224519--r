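# Random rigid-body transform (uniform rotation via QR of a Gaussian
# matrix, translation ~ N(0, shift_sd)). Used so synthetic fixtures are not
# axis-aligned.
random_rigid_transform <- function(shift_sd = 20) {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rotation = rot, translation = rnorm(3, sd = shift_sd))
}

apply_rigid <- function(atoms, transform) {
  xyz <- coords_matrix(atoms) %*% t(transform$rotation)
  atoms$x <- xyz[, 1] + transform$translation[1]
  atoms$y <- xyz[, 2] + transform$translation[2]
  atoms$z <- xyz[, 3] + transform$translation[3]
  atoms
}

atom_row <- function(serial, atom_name, residue_name, chain_id, residue_seq,
                     xyz, record = "ATOM", element = "C") {
  tibble(frame = 1L, record = record, serial = as.integer(serial),
         atom_name = atom_name, residue_name = residue_name,
         chain_id = chain_id, residue_seq = as.integer(residue_seq),
         insertion_code = "", x = xyz[1], y = xyz[2], z = xyz[3],
         occupancy = 1, b_factor = 0, element = element)
}

#' Build a two-domain C-alpha pseudo-structure with a designed hinge angle
#'
#' Two rigid straight arms of C-alpha atoms meet at a vertex atom; the angle
#' between the arm axes at the vertex equals `angle_deg` exactly before
#' noise. The whole structure is then placed at a random (seeded) rigid-body
#' orientation so downstream code never sees an axis-aligned special case.
#' Residues are numbered 1..(2n+1) on one chain with the vertex at n+1; the
#' matching [hinge_definition()] and the ground-truth angle are returned
#' with the structure.
#'
#' @param angle_deg Designed hinge angle, in (0, 180].
#' @param n_per_domain C-alpha atoms per arm (default 8).
#' @param noise_sd Gaussian positional noise SD in Angstrom (default 0;
#'   ground truth refers to the pre-noise geometry).
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @return List with `structure` (atom tibble), `hinge`
#'   ([hinge_definition()]) and `angle_deg` (ground truth).
#' @examples
#' s <- make_hinge_structure(angle_deg = 35, seed = 7)
#' hinge_angle(s$structure, s$hinge)
#' @export
make_hinge_structure <- function(angle_deg, n_per_domain = 8, noise_sd = 0,
                                 seed = 1) {
  if (!(angle_deg > 0 && angle_deg <= 180)) {
    abort("hinge angle must be in (0, 180] degrees")
  }
  if (n_per_domain < 1) abort("need at least one atom per domain")
  withr::with_seed(seed, {
    th <- angle_deg * pi / 180
    u1 <- c(1, 0, 0)
    u2 <- c(cos(th), sin(th), 0)
    spacing <- 3.8  # typical C-alpha virtual bond length
    n <- n_per_domain
    rows <- list()
    for (i in seq_len(n)) {          # domain 1, residue 1 outermost
      rows[[i]] <- atom_row(i, "CA", "ALA", "A", i, (n - i + 1) * spacing * u1)
    }
    rows[[n + 1]] <- atom_row(n + 1, "CA", "GLY", "A", n + 1, c(0, 0, 0))
    for (i in seq_len(n)) {          # domain 2, residue 2n+1 outermost
      rows[[n + 1 + i]] <- atom_row(n + 1 + i, "CA", "ALA", "A", n + 1 + i,
                                    i * spacing * u2)
    }
    st <- dplyr::bind_rows(rows)
    if (noise_sd > 0) {
      st$x <- st$x + rnorm(nrow(st), sd = noise_sd)
      st$y <- st$y + rnorm(nrow(st), sd = noise_sd)
      st$z <- st$z + rnorm(nrow(st), sd = noise_sd)
    }
    st <- apply_rigid(st, random_rigid_transform())
    list(
      structure = st,
      hinge = hinge_definition("A", c(1L, n + 1L, 2L * n + 1L)),
      angle_deg = angle_deg
    )
  })
}

#' Build a trajectory in which pseudo-glycan chains switch configuration
#'
#' Emulates the statistical structure of a glycosylated-Fc simulation at toy
#' scale: a fixed grid of reference-domain residues (chain `"A"`, single
#' C-alpha each, 10 Angstrom apart) plays the C-gamma-2 domain, and each
#' glycan chain is seven single-atom HETATM residues (NAG/NAG/BMA/MAN x 4).
#' Per frame and per chain a state is drawn (or designed), and probe
#' residues 2..6 are placed so that exactly `contact_bound` (bound state) or
#' `contact_loose` (loose state) reference residues fall within 3 Angstrom
#' — the designed contact count is realised exactly, so classification can
#' be checked against ground truth frame by frame.
#'
#' Defaults emulate the reported study conditions: two glycan chains, one
#' almost always tightly associated (loose 3.3% of frames), the other
#' frequently loose (34.5%).
#'
#' @param n_frames Number of frames.
#' @param p_loose Named numeric vector of per-chain loose-state
#'   probabilities (sampling mode). Names become chain ids (single
#'   characters).
#' @param n_loose Optional named integer vector: exact number of loose
#'   frames per chain (design mode; overrides `p_loose`). Loose frames are
#'   the first `n_loose` frames of each chain.
#' @param contact_bound,contact_loose Reference-residue contact counts
#'   realised in the bound / loose state; must satisfy
#'   `contact_loose <= loose_threshold < contact_bound` and be at most 5
#'   (one probe residue per contacted reference residue).
#' @param loose_threshold Threshold the downstream classifier will use
#'   (default 2), checked against the designed counts.
#' @param seed Integer seed.
#' @return List with `trajectory` (atom tibble), `topologies` (named list of
#'   [glycan_topology()]), `spec` (the matching [state_spec()]), and `truth`
#'   (tibble `frame`, `chain`, `state`).
#' @export
make_glycan_state_trajectory <- function(n_frames = 100,
                                         p_loose = c(U = 0.033, V = 0.345),
                                         n_loose = NULL,
                                         contact_bound = 4L,
                                         contact_loose = 1L,
                                         loose_threshold = 2L,
                                         seed = 1) {
  if (n_frames < 1) abort("need at least one frame")
  if (contact_loose > loose_threshold || contact_bound <= loose_threshold) {
    abort("designed contact counts are inconsistent with loose_threshold")
  }
  if (contact_bound > 5 || contact_loose < 0) {
    abort("designed contact counts must be between 0 and 5")
  }
  chains <- if (!is.null(n_loose) && !is.null(names(n_loose))) {
    names(n_loose)
  } else {
    names(p_loose) %||% LETTERS[21:(20 + length(p_loose))]
  }
  if (!is.null(n_loose)) {
    if (is.null(names(n_loose))) names(n_loose) <- chains
    if (length(n_loose) != length(chains)) {
      abort("n_loose needs one entry per glycan chain")
    }
    if (any(n_loose < 0 | n_loose > n_frames)) {
      abort("n_loose must be between 0 and n_frames")
    }
  }
  n_ref <- 8L
  glyc_names <- c("NAG", "NAG", "BMA", "MAN", "MAN", "MAN", "MAN")

  withr::with_seed(seed, {
    # per-chain frame labels
    truth <- purrr::imap_dfr(setNames(seq_along(chains), chains),
                             function(ci, ch) {
      loose <- if (!is.null(n_loose)) {
        seq_len(n_frames) <= n_loose[[ch]]
      } else {
        stats::runif(n_frames) < p_loose[[ci]]
      }
      tibble(frame = seq_len(n_frames), chain = ch,
             state = ifelse(loose, "loose", "bound"))
    })

    frames <- purrr::map(seq_len(n_frames), function(f) {
      serial <- 0L
      rows <- list()
      nxt <- function(...) {
        serial <<- serial + 1L
        atom_row(serial, ...)
      }
      for (j in seq_len(n_ref)) {   # reference C-gamma-2 grid
        rows[[length(rows) + 1L]] <-
          nxt("CA", "LEU", "A", j, c(10 * (j - 1), 0, 0))
      }
      rows[[length(rows) + 1L]] <-  # attachment Asn, out of contact range
        nxt("CA", "ASN", "A", 297, c(-20, 10, 0))
      for (ci in seq_along(chains)) {
        st <- truth$state[truth$frame == f & truth$chain == chains[ci]]
        k <- if (st == "loose") contact_loose else contact_bound
        side <- if (ci %% 2 == 1) 2 else -2   # z offset separates chains
        for (g in 1:7) {
          pos <- if (g %in% 2:6 && (g - 1) <= k) {
            c(10 * (g - 2), 0, side)          # within 3 A of ref residue g-1
          } else {
            c(10 * (g - 2), 60 + 5 * g, side) # far from the reference grid
          }
          rows[[length(rows) + 1L]] <-
            nxt("C1", glyc_names[g], chains[ci], g, pos, record = "HETATM")
        }
      }
      dplyr::mutate(dplyr::bind_rows(rows), frame = f)
    })
    traj <- dplyr::bind_rows(frames)

    topologies <- setNames(purrr::map(chains, function(ch) {
      glycan_topology(ch, 1:7,
                      attachment = list(chain_id = "A", residue_seq = 297))
    }), chains)
    spec <- state_spec(
      reference = atom_selection(chain_id = "A",
                                 residue_seq = list(c(1, n_ref)),
                                 heavy_only = TRUE),
      probe_indices = 2:6, cutoff = 3.0, loose_threshold = loose_threshold
    )
    list(trajectory = traj, topologies = topologies, spec = spec,
         truth = truth)
  })
}

#' Simulated sensorgram fixture at study-like conditions
#'
#' Thin wrapper over [simulate_sensorgrams()] whose defaults are the
#' apparent hexa-Fc/DC-SIGN kinetics (kon = 6.68e2 M^-1 s^-1, koff =
#' 8.39e-4 s^-1, so KD = 1.26 uM) with a six-step doubling dilution from
#' 16 x KD and a 300 s buffer switch.
#'
#' @param kon,koff,rmax Model parameters.
#' @param top_conc Top analyte concentration (M); default `16 * koff/kon`.
#' @param n_dilutions Number of doubling dilutions.
#' @param t_switch,t_end,dt Schedule parameters (s).
#' @param noise_sd Gaussian noise SD (RU).
#' @param seed Integer seed.
#' @return List with `curves` (sensorgram tibble), `model` and `schedule`.
#' @export
make_sensorgrams <- function(kon = 6.68e2, koff = 8.39e-4, rmax = 100,
                             top_conc = NULL, n_dilutions = 6,
                             t_switch = 300, t_end = 600, dt = 1,
                             noise_sd = 0, seed = 1) {
  model <- langmuir_model(kon, koff, rmax)
  top_conc <- top_conc %||% (16 * model$kd)
  schedule <- injection_schedule(doubling_dilutions(top_conc, n_dilutions),
                                 t_switch = t_switch, t_end = t_end, dt = dt)
  curves <- simulate_sensorgrams(model, schedule, noise_sd = noise_sd,
                                 seed = seed)
  list(curves = curves, model = model, schedule = schedule)
}

#' Peak-list fixture from known glycan compositions
#'
#' @param compositions List of [glycan_composition()] objects.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (0 = exact masses).
#' @param intensities Optional intensities (recycled); default 100.
#' @param seed Integer seed.
#' @inheritParams permethylated_mz
#' @return Tibble with columns `mz`, `intensity`, sorted by `mz`, plus the
#'   true compositions in attribute `"truth"`.
#' @export
make_peak_list <- function(compositions, mz_jitter_sd = 0,
                           intensities = 100, seed = 1,
                           adduct = c("Na", "K")) {
  adduct <- match.arg(adduct)
  if (mz_jitter_sd < 0) abort("mz_jitter_sd must be non-negative")
  mz <- vapply(compositions, permethylated_mz, numeric(1), adduct = adduct)
  withr::with_seed(seed, {
    if (mz_jitter_sd > 0) mz <- mz + rnorm(length(mz), sd = mz_jitter_sd)
    out <- tibble(mz = mz,
                  intensity = rep_len(intensities, length(mz)))
  })
  out <- dplyr::arrange(out, .data$mz)
  attr(out, "truth") <- compositions
  out
}
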