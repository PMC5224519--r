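#' Define the three anchors of an interdomain hinge angle
#'
#' The D1-D2 hinge angle of an Fc-gamma-receptor-like two-domain structure is
#' the angle at a vertex residue between vectors to one anchor residue in
#' each domain. Anchors are identified by chain, author residue number and
#' atom name; the backbone C-alpha is the conventional choice and the
#' default. For the high-affinity receptor Fc-gamma-RI the customary triplet
#' is Ile96 / Gly103 / Ser110 of the receptor chain.
#'
#' @param chain_id Chain id(s); length 1 (recycled) or 3.
#' @param residue_seq Integer vector of length 3: outer-D1, vertex, outer-D2.
#' @param atom_name Atom name(s); length 1 or 3. Default `"CA"`.
#' @return A `hinge_definition` tibble with one row per anchor.
#' @examples
#' hinge_definition("A", c(96, 103, 110))
#' @export
hinge_definition <- function(chain_id, residue_seq, atom_name = "CA") {
  if (length(residue_seq) != 3L) {
    abort("a hinge is defined by exactly three residues (outer, vertex, outer)")
  }
  out <- tibble(
    role = c("outer1", "vertex", "outer2"),
    chain_id = rep_len(chain_id, 3L),
    residue_seq = as.integer(residue_seq),
    atom_name = rep_len(atom_name, 3L)
  )
  if (anyDuplicated(out[, -1])) {
    abort("hinge anchors must be three distinct atoms")
  }
  class(out) <- c("hinge_definition", class(out))
  out
}

anchor_xyz <- function(model, anchor, frame = NULL) {
  hit <- model[model$chain_id == anchor$chain_id &
                 model$residue_seq == anchor$residue_seq &
                 model$atom_name == anchor$atom_name, , drop = FALSE]
  if (nrow(hit) == 0) {
    where <- if (is.null(frame)) "" else paste0(" in frame ", frame)
    abort(paste0("hinge anchor not found", where, ": chain ", anchor$chain_id,
                 " residue ", anchor$residue_seq, " atom ", anchor$atom_name))
  }
  c(hit$x[1], hit$y[1], hit$z[1])
}

#' Measure the hinge angle of a single model
#'
#' Computes the angle (degrees, in \[0, 180\]) at the vertex anchor between
#' the vectors pointing to the two outer anchors. The statistic is invariant
#' under rigid-body rotation and translation and symmetric in the two outer
#' anchors.
#'
#' @param model Atom tibble (one frame).
#' @param hinge A [hinge_definition()].
#' @return Angle in degrees.
#' @examples
#' s <- make_hinge_structure(angle_deg = 50, seed = 1)
#' hinge_angle(s$structure, s$hinge)
#' @export
hinge_angle <- function(model, hinge) {
  stopifnot(inherits(hinge, "hinge_definition"))
  p1 <- anchor_xyz(model, hinge[1, ])
  pv <- anchor_xyz(model, hinge[2, ])
  p2 <- anchor_xyz(model, hinge[3, ])
  v1 <- p1 - pv
  v2 <- p2 - pv
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Hinge angle along a trajectory
#'
#' @param trajectory Multi-frame atom tibble.
#' @param hinge A [hinge_definition()].
#' @param frame_window Optional inclusive `c(first, last)` frame window;
#'   `NULL` analyses every frame.
#' @return Tibble with columns `frame`, `angle_deg`.
#' @export
hinge_angle_series <- function(trajectory, hinge, frame_window = NULL) {
  frames <- window_frames(trajectory, frame_window)
  angles <- vapply(frames, function(f) {
    hinge_angle(get_frame(trajectory, f), hinge)
  }, numeric(1))
  tibble(frame = frames, angle_deg = angles)
}

window_frames <- function(trajectory, frame_window) {
  frames <- sort(unique(trajectory$frame %||% 1L))
  if (!is.null(frame_window)) {
    frames <- frames[frames >= frame_window[1] & frames <= frame_window[2]]
  }
  if (length(frames) == 0) abort("frame window selects no frames")
  frames
}

#' Specify a contact count between two selections
#'
#' Contacts are inter-selection heavy-atom pairs within `cutoff` Angstrom
#' (inclusive, `d <= cutoff`); hydrogens/deuteriums are always excluded,
#' matching the convention that ~3 Angstrom is a heavy-atom
#' (donor-acceptor) hydrogen-bonding distance. `count_unit` chooses between
#' counting distinct residues of selection B with at least one qualifying
#' contact (`"residues-of-b"`, the default) and counting qualifying atom
#' pairs (`"atom-pairs"`).
#'
#' @param selection_a,selection_b [atom_selection()] objects.
#' @param cutoff Distance cutoff in Angstrom (default 3.0).
#' @param count_unit `"residues-of-b"` or `"atom-pairs"`.
#' @return A `contact_spec` object.
#' @export
contact_spec <- function(selection_a, selection_b, cutoff = 3.0,
                         count_unit = c("residues-of-b", "atom-pairs")) {
  if (cutoff <= 0) abort("contact cutoff must be positive")
  structure(
    list(selection_a = selection_a, selection_b = selection_b,
         cutoff = cutoff, count_unit = match.arg(count_unit)),
    class = "contact_spec"
  )
}

coords_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

cross_dist <- function(a, b) {
  # squared cross-distance matrix, vectorised
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Count contacts between two selections in one model
#'
#' @param model Atom tibble (one frame).
#' @param spec A [contact_spec()].
#' @return Integer contact count.
#' @export
contact_count <- function(model, spec) {
  stopifnot(inherits(spec, "contact_spec"))
  a <- drop_hydrogens(select_atoms(model, spec$selection_a, require_nonempty = TRUE))
  b <- drop_hydrogens(select_atoms(model, spec$selection_b, require_nonempty = TRUE))
  if (nrow(a) == 0 || nrow(b) == 0) abort("selection has no heavy atoms")
  d <- cross_dist(coords_matrix(a), coords_matrix(b))
  if (max(d) > 500) {
    warn("interatomic distance exceeds 500 Angstrom; frames are assumed whole (no periodic imaging is applied)")
  }
  hit <- d <= spec$cutoff
  if (spec$count_unit == "atom-pairs") {
    return(sum(hit))
  }
  bres <- paste(b$chain_id, b$residue_seq, b$insertion_code, sep = "\r")
  length(unique(bres[colSums(hit) > 0]))
}

drop_hydrogens <- function(atoms) {
  atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
}

#' Contact counts along a trajectory
#'
#' @inheritParams hinge_angle_series
#' @param spec A [contact_spec()].
#' @return Tibble with columns `frame`, `contacts`.
#' @export
contact_series <- function(trajectory, spec, frame_window = NULL) {
  frames <- window_frames(trajectory, frame_window)
  counts <- vapply(frames, function(f) {
    contact_count(get_frame(trajectory, f), spec)
  }, numeric(1))
  tibble(frame = frames, contacts = as.integer(counts))
}

#' Per-residue contact frequency over a trajectory
#'
#' For each residue of selection B, the number and fraction of analysed
#' frames in which it has at least one heavy-atom contact (within the
#' cutoff) with selection A — the per-residue view used to map which
#' receptor residues an Fc surface touches persistently.
#'
#' @inheritParams contact_series
#' @return Tibble with columns `chain_id`, `residue_seq`, `residue_name`,
#'   `n_frames_contact`, `frequency`.
#' @export
contact_frequency <- function(trajectory, spec, frame_window = NULL) {
  frames <- window_frames(trajectory, frame_window)
  tallies <- purrr::map(frames, function(f) {
    model <- get_frame(trajectory, f)
    a <- drop_hydrogens(select_atoms(model, spec$selection_a, require_nonempty = TRUE))
    b <- drop_hydrogens(select_atoms(model, spec$selection_b, require_nonempty = TRUE))
    d <- cross_dist(coords_matrix(a), coords_matrix(b))
    hit <- colSums(d <= spec$cutoff) > 0
    tibble(chain_id = b$chain_id, residue_seq = b$residue_seq,
           residue_name = b$residue_name, contact = hit) |>
      dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
      dplyr::summarise(contact = any(.data$contact), .groups = "drop")
  })
  dplyr::bind_rows(tallies) |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
    dplyr::summarise(n_frames_contact = sum(.data$contact), .groups = "drop") |>
    dplyr::mutate(frequency = .data$n_frames_contact / length(frames)) |>
    dplyr::arrange(.data$chain_id, .data$residue_seq)
}
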