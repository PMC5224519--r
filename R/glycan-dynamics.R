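#' Describe a Man5GlcNAc2 glycan chain within a structure
#'
#' Maps the canonical seven-residue indexing of the high-mannose
#' Man5GlcNAc2 N-glycan onto residues of a structure: 1-2 the
#' di-N-acetylchitobiose core GlcNAcs (`NAG`), 3 the beta-mannose (`BMA`),
#' 4 the alpha1-3 branch mannose, 5 the alpha1-6 branch mannose, 6-7 the
#' terminal mannoses of the alpha1-6 arm (`MAN`). The attachment asparagine
#' (canonically Asn297 of the heavy chain) is recorded for provenance.
#'
#' @param chain_id Chain holding the glycan residues (length 1 or 7).
#' @param residue_seq Integer vector of length 7, author numbering, in
#'   glycan index order 1..7.
#' @param residue_name Residue names, default
#'   `c("NAG","NAG","BMA","MAN","MAN","MAN","MAN")`.
#' @param attachment List with `chain_id` and `residue_seq` of the
#'   attachment Asn, or `NULL`.
#' @return A `glycan_topology` tibble (one row per glycan index).
#' @export
glycan_topology <- function(chain_id, residue_seq,
                            residue_name = c("NAG", "NAG", "BMA", "MAN",
                                             "MAN", "MAN", "MAN"),
                            attachment = NULL) {
  if (length(residue_seq) != 7L) {
    abort("Man5GlcNAc2 topology maps exactly 7 residues (indices 1..7)")
  }
  if (!all(residue_name %in% c("NAG", "BMA", "MAN"))) {
    abort("glycan residue names must be NAG, BMA or MAN")
  }
  out <- tibble(
    glycan_index = 1:7,
    chain_id = rep_len(chain_id, 7L),
    residue_seq = as.integer(residue_seq),
    residue_name = rep_len(residue_name, 7L)
  )
  if (anyDuplicated(out[, c("chain_id", "residue_seq")])) {
    abort("glycan topology residues must be distinct")
  }
  attr(out, "attachment") <- attachment
  class(out) <- c("glycan_topology", class(out))
  out
}

#' Parameters of the two-state glycan configuration classifier
#'
#' Per frame, the number of reference-domain residues (normally the C-gamma-2
#' domain of the glycan-bearing heavy chain) with at least one heavy atom
#' within `cutoff` Angstrom of glycan residues `probe_indices` is counted; a
#' frame with `loose_threshold` or fewer such residues is labelled `"loose"`
#' (the configuration only loosely associated with the domain), otherwise
#' `"bound"`.
#'
#' @param reference An [atom_selection()] for the reference domain residues.
#' @param probe_indices Glycan indices probed (default `2:6`: core GlcNAc-2
#'   through the alpha1-6 arm mannose-6). Set to `3:6` to start at the
#'   beta-mannose instead.
#' @param cutoff Contact cutoff in Angstrom (default 3.0).
#' @param loose_threshold Maximum contact count still labelled loose
#'   (default 2).
#' @return A `state_spec` object.
#' @export
state_spec <- function(reference, probe_indices = 2:6, cutoff = 3.0,
                       loose_threshold = 2L) {
  if (!all(probe_indices %in% 1:7)) {
    abort("probe indices must be a subset of 1..7")
  }
  if (loose_threshold < 0) abort("loose_threshold must be >= 0")
  structure(
    list(reference = reference, probe_indices = as.integer(probe_indices),
         cutoff = cutoff, loose_threshold = as.integer(loose_threshold)),
    class = "state_spec"
  )
}

probe_selection <- function(topology, spec) {
  rows <- topology[topology$glycan_index %in% spec$probe_indices, ]
  atom_selection(chain_id = unique(rows$chain_id),
                 residue_seq = rows$residue_seq,
                 heavy_only = TRUE)
}

#' Classify the glycan configuration of one frame
#'
#' @param model Atom tibble (one frame).
#' @param topology A [glycan_topology()].
#' @param spec A [state_spec()].
#' @return One-row tibble: `contacts`, `state` (`"bound"`/`"loose"`).
#' @export
classify_frame <- function(model, topology, spec) {
  stopifnot(inherits(topology, "glycan_topology"), inherits(spec, "state_spec"))
  check_topology_resolvable(model, topology, spec)
  cs <- contact_spec(probe_selection(topology, spec), spec$reference,
                     cutoff = spec$cutoff, count_unit = "residues-of-b")
  n <- contact_count(model, cs)
  tibble(contacts = as.integer(n),
         state = ifelse(n <= spec$loose_threshold, "loose", "bound"))
}

check_topology_resolvable <- function(model, topology, spec) {
  rows <- topology[topology$glycan_index %in% spec$probe_indices, ]
  for (i in seq_len(nrow(rows))) {
    hit <- model$chain_id == rows$chain_id[i] &
      model$residue_seq == rows$residue_seq[i]
    if (!any(hit)) {
      abort(paste0("glycan topology index ", rows$glycan_index[i],
                   " (chain ", rows$chain_id[i], " residue ",
                   rows$residue_seq[i], ") not found in model"))
    }
  }
  invisible(TRUE)
}

#' Classify glycan configurations along a trajectory
#'
#' Applies [classify_frame()] to every frame in the window for each glycan
#' chain.
#'
#' @param trajectory Multi-frame atom tibble.
#' @param topologies A single [glycan_topology()] or a named list of them
#'   (one per glycan chain).
#' @param spec A [state_spec()].
#' @param frame_window Optional inclusive `c(first, last)` window.
#' @return Tibble with columns `frame`, `chain`, `contacts`, `state`.
#' @export
classify_glycan_states <- function(trajectory, topologies, spec,
                                   frame_window = NULL) {
  if (inherits(topologies, "glycan_topology")) {
    topologies <- list(glycan = topologies)
  }
  if (is.null(names(topologies)) || any(names(topologies) == "")) {
    names(topologies) <- paste0("chain", seq_along(topologies))
  }
  frames <- window_frames(trajectory, frame_window)
  purrr::map_dfr(frames, function(f) {
    model <- get_frame(trajectory, f)
    purrr::imap_dfr(topologies, function(topo, nm) {
      dplyr::mutate(classify_frame(model, topo, spec),
                    frame = f, chain = nm, .before = 1)
    })
  })
}

#' Summarise per-chain state fractions
#'
#' @param states Classification tibble from [classify_glycan_states()].
#' @return Tibble with columns `chain`, `n_frames`, `f_bound`, `f_loose`
#'   (fractions sum to 1 per chain).
#' @export
state_fractions <- function(states) {
  if (nrow(states) == 0) abort("no classified frames (empty window)")
  states |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      f_bound = mean(.data$state == "bound"),
      f_loose = mean(.data$state == "loose"),
      .groups = "drop"
    )
}

#' Define the entrance plane of the Fc cavity
#'
#' The opening through which a lectin carbohydrate-recognition domain must
#' reach the glycan is modelled as an ellipse in a plane: `origin` is the
#' ellipse centre, `normal` points out of the cavity, and `major_axis` is an
#' in-plane direction along the major semi-axis. All coordinates in nm.
#'
#' @param origin,normal,major_axis Numeric length-3 vectors (nm; directions
#'   are normalised internally).
#' @return An `entrance_plane` object with an orthonormal in-plane basis.
#' @export
entrance_plane <- function(origin = c(0, 0, 0), normal = c(0, 0, 1),
                           major_axis = c(1, 0, 0)) {
  n <- normal / sqrt(sum(normal^2))
  u <- major_axis - sum(major_axis * n) * n
  if (sqrt(sum(u^2)) < 1e-12) abort("major_axis must not be parallel to normal")
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  structure(list(origin = origin, normal = n, u = u, v = v),
            class = "entrance_plane")
}

#' Geometry of the lectin-accessibility test
#'
#' Defaults encode a roughly elliptical cavity entrance of 2 nm x 3.5 nm
#' (semi-axes 1.0 and 1.75 nm) and a carbohydrate-recognition domain
#' approximated by a 3 nm diameter sphere (probe radius 1.5 nm), engaging a
#' mannose when the probe surface comes within 3 Angstrom (0.3 nm).
#'
#' @param semi_major,semi_minor Entrance ellipse semi-axes (nm).
#' @param probe_radius Probe sphere radius (nm).
#' @param contact_distance Required probe-surface-to-atom distance (nm).
#' @return An `accessibility_geometry` object.
#' @export
accessibility_geometry <- function(semi_major = 1.75, semi_minor = 1.0,
                                   probe_radius = 1.5,
                                   contact_distance = 0.3) {
  if (semi_major <= 0 || semi_minor <= 0) abort("semi-axes must be positive")
  if (probe_radius <= 0) abort("probe radius must be positive")
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 probe_radius = probe_radius,
                 contact_distance = contact_distance),
            class = "accessibility_geometry")
}

# 2D distance from point (p, q) to the boundary of an axis-aligned ellipse
# with semi-axes (a, b); used only for points outside the ellipse.
ellipse_boundary_distance <- function(p, q, a, b) {
  p <- abs(p); q <- abs(q)
  f <- function(th) (a * cos(th) - p)^2 + (b * sin(th) - q)^2
  opt <- optimize(f, c(0, pi / 2), tol = 1e-12)
  sqrt(opt$objective)
}

#' Can a spherical lectin probe reach a target atom through the cavity
#' entrance?
#'
#' The probe centre is constrained to the outside half-space of the entrance
#' plane and to project (along the entrance normal) into the entrance
#' ellipse shrunk by the probe radius along each semi-axis — the set of
#' centre positions from which the sphere can sit in the opening. If either
#' shrunk semi-axis is non-positive, the probe cannot pass the entrance at
#' all and the target is reported as blocked. Otherwise the minimal
#' achievable probe-surface-to-target distance (`clearance`) is computed in
#' closed form over that convex set, and the target is `accessible` when the
#' clearance is within the contact distance (`margin = contact_distance -
#' clearance >= 0`).
#'
#' @param target Numeric length-3 target coordinates (nm), e.g. the terminal
#'   alpha1-6-arm mannose centroid.
#' @param plane An [entrance_plane()].
#' @param geometry An [accessibility_geometry()].
#' @return One-row tibble: `accessible`, `blocked`, `clearance` (nm; minimal
#'   probe-surface-to-atom distance, negative if the surface can overlap the
#'   target position), `margin` (nm).
#' @export
accessibility_check <- function(target, plane, geometry) {
  stopifnot(inherits(plane, "entrance_plane"),
            inherits(geometry, "accessibility_geometry"))
  a <- geometry$semi_major - geometry$probe_radius
  b <- geometry$semi_minor - geometry$probe_radius
  if (a <= 0 || b <= 0) {
    return(tibble(accessible = FALSE, blocked = TRUE,
                  clearance = Inf, margin = -Inf))
  }
  rel <- target - plane$origin
  h <- sum(rel * plane$normal)            # signed height (outside > 0)
  p <- sum(rel * plane$u)                 # in-plane major-axis coordinate
  q <- sum(rel * plane$v)                 # in-plane minor-axis coordinate
  inside_ellipse <- (p / a)^2 + (q / b)^2 <= 1
  planar <- if (inside_ellipse) 0 else ellipse_boundary_distance(p, q, a, b)
  centre_dist <- if (h >= 0 && inside_ellipse) {
    0                                      # target inside the feasible set
  } else if (h >= 0) {
    planar
  } else {
    sqrt(h^2 + planar^2)
  }
  clearance <- centre_dist - geometry$probe_radius
  margin <- geometry$contact_distance - clearance
  # 1e-9 nm numerical tolerance on the boundary
  tibble(accessible = margin >= -1e-9, blocked = FALSE,
         clearance = clearance, margin = margin)
}
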