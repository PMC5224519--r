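#' Read a PDB structure or multi-model trajectory into a tidy atom table
#'
#' Parses fixed-column PDB files (via [bio3d::read.pdb()]) into a tibble with
#' one row per atom per frame. `ATOM` and `HETATM` records are both retained,
#' so glycan residues (`NAG`, `BMA`, `MAN`, ...) are first-class. Each `MODEL`
#' block becomes one frame; a file without `MODEL` records yields a single
#' frame. Alternate locations are resolved to the highest-occupancy conformer
#' (tie broken by file order).
#'
#' @param path Path to a PDB file.
#' @param multi_model Read all `MODEL` blocks as trajectory frames
#'   (default `TRUE`). With `FALSE` only the first model is kept.
#' @param frame_spacing Optional time between frames in ns, stored as the
#'   `frame_spacing_ns` attribute.
#'
#' @return A tibble with columns `frame`, `record`, `serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_seq` (author numbering, preserved
#'   exactly), `insertion_code` (`""` if none), `x`, `y`, `z` (Angstrom),
#'   `occupancy`, `b_factor`, `element`.
#'
#' @examples
#' traj <- make_glycan_state_trajectory(n_frames = 3, seed = 1)$trajectory
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(traj, f)
#' identical(nrow(read_pdb(f)), nrow(traj))
#' @export
read_pdb <- function(path, multi_model = TRUE, frame_spacing = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  raw <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", raw)
  if (!any(is_atom)) {
    abort(paste0("no ATOM/HETATM records in ", path, " (empty structure)"))
  }
  validate_pdb_coords(raw, is_atom, path)
  validate_model_blocks(raw, is_atom, path)

  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = multi_model, rm.alt = FALSE,
                    verbose = FALSE, hex = FALSE)
  ))
  atom <- pdb$atom
  keep <- resolve_altloc(atom)
  atom <- atom[keep, , drop = FALSE]
  xyz <- unclass(pdb$xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  xyz <- xyz[, cols, drop = FALSE]
  nf <- if (multi_model) nrow(xyz) else 1L

  base <- tibble(
    record = atom$type,
    serial = as.integer(atom$eleno),
    atom_name = atom$elety,
    residue_name = atom$resid,
    chain_id = ifelse(is.na(atom$chain), "", atom$chain),
    residue_seq = as.integer(atom$resno),
    insertion_code = ifelse(is.na(atom$insert), "", atom$insert),
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    b_factor = ifelse(is.na(atom$b), 0, atom$b),
    element = infer_element(atom$elesy, atom$elety)
  )
  frames <- purrr::map(seq_len(nf), function(f) {
    v <- xyz[f, ]
    dplyr::mutate(base,
      frame = f,
      x = v[c(TRUE, FALSE, FALSE)],
      y = v[c(FALSE, TRUE, FALSE)],
      z = v[c(FALSE, FALSE, TRUE)]
    )
  })
  out <- dplyr::bind_rows(frames)
  out <- dplyr::select(out, "frame", "record", "serial", "atom_name",
                       "residue_name", "chain_id", "residue_seq",
                       "insertion_code", "x", "y", "z", "occupancy",
                       "b_factor", "element")
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z)) {
    abort(paste0("non-finite coordinates after parsing ", path))
  }
  attr(out, "frame_spacing_ns") <- frame_spacing
  out
}

# Coordinate fields live in columns 31-54; a field that does not parse as a
# number is reported with its line number.
validate_pdb_coords <- function(raw, is_atom, path) {
  lines <- raw[is_atom]
  nums <- which(is_atom)
  for (off in c(31L, 39L, 47L)) {
    field <- substr(lines, off, off + 7L)
    bad <- is.na(suppressWarnings(as.numeric(field)))
    if (any(bad)) {
      abort(paste0("malformed coordinate field on line ", nums[which(bad)[1]],
                   " of ", path, ": '", field[which(bad)[1]], "'"))
    }
  }
  invisible(TRUE)
}

validate_model_blocks <- function(raw, is_atom, path) {
  starts <- grepl("^MODEL", raw)
  if (!any(starts)) return(invisible(TRUE))
  block <- cumsum(starts)
  counts <- table(block[is_atom & block > 0])
  if (length(unique(as.integer(counts))) > 1L) {
    abort(paste0("MODEL blocks in ", path, " have differing atom counts (",
                 paste(as.integer(counts), collapse = ", "),
                 "); trajectory frames must share one topology"))
  }
  invisible(TRUE)
}

# Highest occupancy wins; ties go to the first-listed conformer.
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  if (!anyDuplicated(key)) return(seq_len(nrow(atom)))
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(key, -occ, seq_along(key))
  keep <- ord[!duplicated(key[ord])]
  sort(keep)
}

infer_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  need <- el == ""
  if (any(need)) {
    nm <- gsub("[^A-Za-z]", "", elety[need])
    guess <- toupper(substr(nm, 1, 1))
    guess[grepl("^[0-9]*H", elety[need])] <- "H"
    guess[grepl("^[0-9]*D[A-Z]", toupper(elety[need]))] <- "D"
    el[need] <- guess
  }
  el
}

#' Write a tidy atom table to a (multi-model) PDB file
#'
#' Writes fixed-column PDB with coordinates to 3 decimals; trajectories with
#' more than one frame are written as `MODEL`/`ENDMDL` blocks. Record types
#' (`ATOM`/`HETATM`) are preserved.
#'
#' @param trajectory Atom tibble as returned by [read_pdb()] or the
#'   synthetic generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(trajectory, path) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    abort("cannot write an empty trajectory")
  }
  traj <- check_topology(trajectory)
  if (any(nchar(traj$chain_id) > 1L)) {
    abort("PDB chain identifiers must be a single character")
  }
  frames <- sort(unique(traj$frame))
  first <- traj[traj$frame == frames[1], , drop = FALSE]
  xyz <- t(vapply(frames, function(f) {
    m <- traj[traj$frame == f, , drop = FALSE]
    as.vector(rbind(m$x, m$y, m$z))
  }, numeric(3L * nrow(first))))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = first$record, eleno = first$serial, elety = first$atom_name,
    resid = first$residue_name, chain = first$chain_id,
    resno = first$residue_seq, insert = first$insertion_code,
    o = first$occupancy, b = first$b_factor, elesy = first$element,
    end = TRUE
  )
  invisible(path)
}

# All frames must carry the same atom identity sequence.
check_topology <- function(traj) {
  if (!"frame" %in% names(traj)) {
    traj <- dplyr::mutate(traj, frame = 1L)
  }
  ids <- split(
    paste(traj$record, traj$chain_id, traj$residue_seq, traj$insertion_code,
          traj$atom_name, sep = "\r"),
    traj$frame
  )
  ref <- ids[[1]]
  same <- vapply(ids, function(v) identical(v, ref), logical(1))
  if (!all(same)) {
    abort("trajectory frames do not share one atom topology")
  }
  traj
}

#' Count the frames of a trajectory tibble
#' @param trajectory Atom tibble with a `frame` column.
#' @return Integer number of frames.
#' @export
n_frames <- function(trajectory) {
  if (!"frame" %in% names(trajectory)) return(1L)
  dplyr::n_distinct(trajectory$frame)
}

#' Extract a single frame from a trajectory
#' @inheritParams n_frames
#' @param frame Frame index to keep.
#' @return Atom tibble restricted to one frame.
#' @export
get_frame <- function(trajectory, frame) {
  if (!"frame" %in% names(trajectory)) return(trajectory)
  out <- dplyr::filter(trajectory, .data$frame == !!frame)
  if (nrow(out) == 0) abort(paste0("no such frame: ", frame))
  out
}

#' Define an atom selection
#'
#' A declarative filter over the atom table: chain, author-numbered residue
#' ranges, residue-name and atom-name whitelists, and an optional
#' heavy-atoms-only flag (drops element H and D). `NULL` fields are
#' wildcards. Resolution is deterministic and order-stable: matching atoms
#' are returned in the order they appear in the model.
#'
#' @param chain_id Chain identifier(s), or `NULL` for any chain.
#' @param residue_seq Residue numbers: an integer vector, or a list of
#'   inclusive `c(lo, hi)` ranges, or `NULL` for all residues.
#' @param residue_name Residue name whitelist, or `NULL`.
#' @param atom_name Atom name whitelist, or `NULL`.
#' @param heavy_only If `TRUE`, exclude hydrogens and deuteriums.
#' @return An object of class `atom_selection`.
#' @examples
#' sel <- atom_selection(chain_id = "A", residue_seq = list(c(96, 110)),
#'                       atom_name = "CA")
#' @export
atom_selection <- function(chain_id = NULL, residue_seq = NULL,
                           residue_name = NULL, atom_name = NULL,
                           heavy_only = FALSE) {
  structure(
    list(chain_id = chain_id, residue_seq = residue_seq,
         residue_name = residue_name, atom_name = atom_name,
         heavy_only = isTRUE(heavy_only)),
    class = "atom_selection"
  )
}

#' Resolve an atom selection against a model or frame
#'
#' @param model Atom tibble (one frame, or pass `trajectory` rows of a single
#'   frame via [get_frame()]).
#' @param selection An [atom_selection()].
#' @param require_nonempty Error if the selection resolves to zero atoms.
#' @return The matching rows of `model`, in model order.
#' @export
select_atoms <- function(model, selection, require_nonempty = FALSE) {
  stopifnot(inherits(selection, "atom_selection"))
  keep <- rep(TRUE, nrow(model))
  if (!is.null(selection$chain_id)) {
    keep <- keep & model$chain_id %in% selection$chain_id
  }
  if (!is.null(selection$residue_seq)) {
    rs <- selection$residue_seq
    if (is.list(rs)) {
      in_range <- rep(FALSE, nrow(model))
      for (r in rs) {
        in_range <- in_range |
          (model$residue_seq >= r[1] & model$residue_seq <= r[2])
      }
      keep <- keep & in_range
    } else {
      keep <- keep & model$residue_seq %in% rs
    }
  }
  if (!is.null(selection$residue_name)) {
    keep <- keep & model$residue_name %in% selection$residue_name
  }
  if (!is.null(selection$atom_name)) {
    keep <- keep & model$atom_name %in% selection$atom_name
  }
  if (selection$heavy_only) {
    keep <- keep & !model$element %in% c("H", "D")
  }
  out <- model[keep, , drop = FALSE]
  if (require_nonempty && nrow(out) == 0) {
    abort("selection resolved to zero atoms")
  }
  out
}
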