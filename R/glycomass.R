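# Monoisotopic atomic masses (CODATA/AME-derived standard values, Da).
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  Na = 22.9897692809,
  K = 38.96370668
)

# Elemental formulas (atom counts) of glycosyl residues as they occur
# in-chain (monosaccharide minus water), before permethylation, plus the
# number of methylation sites each carries in a fully permethylated glycan
# (free hydroxyls + amide NH; NeuAc includes the carboxyl methyl ester).
RESIDUE_ELEMENTS <- list(
  Hex    = list(formula = c(C = 6,  H = 10, N = 0, O = 5), n_methyl = 3L),
  HexNAc = list(formula = c(C = 8,  H = 13, N = 1, O = 5), n_methyl = 3L),
  dHex   = list(formula = c(C = 6,  H = 10, N = 0, O = 4), n_methyl = 2L),
  NeuAc  = list(formula = c(C = 11, H = 17, N = 1, O = 8), n_methyl = 5L)
)

formula_mass <- function(counts) {
  sum(counts * ATOMIC_MASS[names(counts)])
}

#' Permethylated residue masses from elemental composition
#'
#' The independent elemental route to the residue masses: each permethylated
#' residue is the native in-chain residue (monosaccharide minus water) with
#' every free hydroxyl/amide hydrogen replaced by a methyl group (+CH2 per
#' site), computed from standard monoisotopic atomic masses. The frozen
#' defaults in [permethylated_mass_table()] are asserted against this
#' function in the package tests.
#'
#' @return Tibble with columns `residue`, `mass` (Da) and the end-group
#'   correction (terminal methylations + H2O) as attribute `"end_group"`.
#' @export
mass_table_from_elements <- function() {
  ch2 <- formula_mass(c(C = 1, H = 2))
  masses <- vapply(RESIDUE_ELEMENTS, function(r) {
    formula_mass(r$formula) + r$n_methyl * ch2
  }, numeric(1))
  out <- tibble(residue = names(masses), mass = unname(masses))
  # reducing + non-reducing terminal methyls and the water of the free
  # reducing end: H2O + 2 CH2
  attr(out, "end_group") <- formula_mass(c(H = 2, O = 1)) + 2 * ch2
  out
}

# Frozen permethylated monoisotopic residue masses (Da); validated against
# mass_table_from_elements() to < 0.001 Da in the test suite.
PERMETHYL_MASS <- c(
  Hex    = 204.099774,
  HexNAc = 245.126323,
  dHex   = 174.089209,
  NeuAc  = 361.173667
)
PERMETHYL_END_GROUP <- 46.041865  # H2O + 2 CH2

#' The frozen permethylated residue mass table
#'
#' @return Tibble with columns `residue`, `mass` (Da); end-group correction
#'   in attribute `"end_group"`.
#' @export
permethylated_mass_table <- function() {
  out <- tibble(residue = names(PERMETHYL_MASS), mass = unname(PERMETHYL_MASS))
  attr(out, "end_group") <- PERMETHYL_END_GROUP
  out
}

#' Define an N-glycan composition
#'
#' Monosaccharide class counts: HexNAc (GlcNAc/GalNAc), Hex (Man/Gal/Glc),
#' dHex (fucose) and NeuAc (sialic acid).
#'
#' @param hexnac,hex,dhex,neuac Non-negative integer counts.
#' @param check_nglycan Require N-glycan plausibility (HexNAc >= 2 and
#'   Hex >= 3, the trimannosyl-chitobiose core).
#' @return A `glycan_composition` object.
#' @examples
#' glycan_composition(hexnac = 4, hex = 5, dhex = 1)
#' @export
glycan_composition <- function(hexnac = 0, hex = 0, dhex = 0, neuac = 0,
                               check_nglycan = FALSE) {
  counts <- c(HexNAc = hexnac, Hex = hex, dHex = dhex, NeuAc = neuac)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("residue counts must be non-negative integers")
  }
  if (sum(counts) < 1) abort("composition must contain at least one residue")
  if (check_nglycan && (hexnac < 2 || hex < 3)) {
    abort("not a plausible N-glycan: need HexNAc >= 2 and Hex >= 3")
  }
  structure(as.integer(counts), names = names(counts),
            class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  paste0(names(nz), unclass(nz), collapse = " ")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Permethylated, sodiated monoisotopic m/z of a glycan composition
#'
#' `m/z = sum(count_i * residue_mass_i) + end-group + adduct`, the mass
#' convention of MALDI-TOF spectra of permethylated N-glycans detected as
#' `[M + Na]+` (or `[M + K]+`).
#'
#' @param composition A [glycan_composition()] (or a named vector with any
#'   of `HexNAc`, `Hex`, `dHex`, `NeuAc`).
#' @param adduct `"Na"` (default) or `"K"`.
#' @param mass_table Residue mass table; defaults to the frozen
#'   [permethylated_mass_table()].
#' @return m/z in Da.
#' @examples
#' permethylated_mz(glycan_composition(hexnac = 4, hex = 5, dhex = 1))
#' # 2244.125 -> the classic core-fucosylated biantennary ion, 2244
#' @export
permethylated_mz <- function(composition, adduct = c("Na", "K"),
                             mass_table = permethylated_mass_table()) {
  adduct <- match.arg(adduct)
  counts <- as_composition_counts(composition)
  masses <- setNames(mass_table$mass, mass_table$residue)
  if (!all(names(counts) %in% names(masses))) {
    abort(paste0("unknown residue class: ",
                 paste(setdiff(names(counts), names(masses)), collapse = ", ")))
  }
  end_group <- attr(mass_table, "end_group") %||% PERMETHYL_END_GROUP
  sum(counts * masses[names(counts)]) + end_group + ATOMIC_MASS[[adduct]]
}

as_composition_counts <- function(composition) {
  if (inherits(composition, "glycan_composition")) {
    return(setNames(as.integer(composition), names(composition)))
  }
  if (is.numeric(composition) && !is.null(names(composition))) {
    bad <- setdiff(names(composition), names(PERMETHYL_MASS))
    if (length(bad)) {
      abort(paste0("unknown residue class: ", paste(bad, collapse = ", ")))
    }
    full <- setNames(integer(length(PERMETHYL_MASS)), names(PERMETHYL_MASS))
    full[names(composition)] <- as.integer(composition)
    return(full)
  }
  abort("composition must be a glycan_composition or a named count vector")
}

#' Enumerate glycan compositions matching an observed m/z
#'
#' Exhaustive search over residue-count bounds for permethylated `[M+Na]+`
#' (or `[M+K]+`) compositions within `tolerance` of the observed m/z,
#' sorted by absolute error. Default bounds cover the plausible N-glycan
#' space (HexNAc 2-8, Hex 3-12, dHex 0-3, NeuAc 0-4).
#'
#' @param mz Observed m/z (Da).
#' @param tolerance Match tolerance (Da), > 0. The default 0.5 Da suits
#'   integer-labelled reflectron spectra.
#' @param bounds Named list of `c(lo, hi)` count bounds per residue class.
#' @param adduct `"Na"` or `"K"`.
#' @return Tibble with count columns, `mz_calc`, `error` and `abs_error`,
#'   sorted by `abs_error`.
#' @export
enumerate_compositions <- function(mz, tolerance = 0.5,
                                   bounds = list(HexNAc = c(2, 8),
                                                 Hex = c(3, 12),
                                                 dHex = c(0, 3),
                                                 NeuAc = c(0, 4)),
                                   adduct = c("Na", "K")) {
  adduct <- match.arg(adduct)
  if (tolerance <= 0) abort("tolerance must be positive")
  bad <- setdiff(names(bounds), names(PERMETHYL_MASS))
  if (length(bad)) {
    abort(paste0("unknown residue class in bounds: ",
                 paste(bad, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    HexNAc = seq(bounds$HexNAc[1] %||% 0, bounds$HexNAc[2] %||% 0),
    Hex = seq(bounds$Hex[1] %||% 0, bounds$Hex[2] %||% 0),
    dHex = seq(bounds$dHex[1] %||% 0, bounds$dHex[2] %||% 0),
    NeuAc = seq(bounds$NeuAc[1] %||% 0, bounds$NeuAc[2] %||% 0)
  )
  grid$mz_calc <- grid$HexNAc * PERMETHYL_MASS[["HexNAc"]] +
    grid$Hex * PERMETHYL_MASS[["Hex"]] +
    grid$dHex * PERMETHYL_MASS[["dHex"]] +
    grid$NeuAc * PERMETHYL_MASS[["NeuAc"]] +
    PERMETHYL_END_GROUP + ATOMIC_MASS[[adduct]]
  grid |>
    dplyr::mutate(error = .data$mz_calc - mz,
                  abs_error = abs(.data$error)) |>
    dplyr::filter(.data$abs_error <= tolerance) |>
    dplyr::arrange(.data$abs_error)
}

#' Annotate a MALDI-TOF peak list with glycan compositions
#'
#' Runs [enumerate_compositions()] for every peak. Peaks without any
#' in-tolerance composition are kept with `assigned = FALSE`.
#'
#' @param peaks Tibble/data frame with columns `mz` and (optionally)
#'   `intensity`, or a numeric m/z vector.
#' @inheritParams enumerate_compositions
#' @return Tibble with one row per (peak, candidate composition) — or per
#'   peak when unassigned — carrying `peak_mz`, `intensity`, `assigned`,
#'   composition counts, `mz_calc` and `error`. Summary counts via
#'   [annotation_summary()].
#' @export
annotate_peaks <- function(peaks, tolerance = 0.5,
                           bounds = list(HexNAc = c(2, 8), Hex = c(3, 12),
                                         dHex = c(0, 3), NeuAc = c(0, 4)),
                           adduct = c("Na", "K")) {
  adduct <- match.arg(adduct)
  if (is.numeric(peaks)) peaks <- tibble(mz = peaks)
  if (!"mz" %in% names(peaks)) abort("peak list must have an 'mz' column")
  if (nrow(peaks) == 0) {
    return(tibble(peak_mz = numeric(), intensity = numeric(),
                  assigned = logical(), HexNAc = integer(), Hex = integer(),
                  dHex = integer(), NeuAc = integer(), mz_calc = numeric(),
                  error = numeric()))
  }
  if (any(peaks$mz <= 0)) abort("peak m/z values must be positive")
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    hits <- enumerate_compositions(peaks$mz[i], tolerance = tolerance,
                                   bounds = bounds, adduct = adduct)
    if (nrow(hits) == 0) {
      return(tibble(peak_mz = peaks$mz[i], intensity = peaks$intensity[i],
                    assigned = FALSE, HexNAc = NA_integer_,
                    Hex = NA_integer_, dHex = NA_integer_,
                    NeuAc = NA_integer_, mz_calc = NA_real_,
                    error = NA_real_))
    }
    dplyr::mutate(hits, peak_mz = peaks$mz[i],
                  intensity = peaks$intensity[i], assigned = TRUE,
                  .before = 1) |>
      dplyr::select(-"abs_error")
  })
}

#' Summarise a peak annotation
#' @param annotations Output of [annotate_peaks()].
#' @return One-row tibble: peaks, assigned/unassigned counts, candidate
#'   compositions.
#' @export
annotation_summary <- function(annotations) {
  tibble(
    n_peaks = dplyr::n_distinct(annotations$peak_mz),
    n_assigned = dplyr::n_distinct(annotations$peak_mz[annotations$assigned]),
    n_unassigned = dplyr::n_distinct(annotations$peak_mz[!annotations$assigned]),
    n_candidates = sum(annotations$assigned)
  )
}

#' Core versus antennal fucose: isobaric at MS1
#'
#' Positional isomers that differ only in where a fucose sits (on the
#' reducing-end GlcNAc of the chitobiose core versus on an antenna, as in
#' Lewis X) have identical compositions and therefore identical MS1 masses;
#' only MS/MS fragmentation can separate them. This helper documents that
#' bookkeeping explicitly.
#'
#' @param composition A [glycan_composition()] with `dHex >= 1`.
#' @inheritParams permethylated_mz
#' @return Tibble with rows `core` and `antennal`, equal `mz`, an
#'   `isobaric` flag and an explanatory `note`.
#' @export
fucose_isomer_masses <- function(composition, adduct = c("Na", "K")) {
  adduct <- match.arg(adduct)
  counts <- as_composition_counts(composition)
  if (counts[["dHex"]] < 1) {
    abort("composition carries no fucose (dHex = 0)")
  }
  m <- permethylated_mz(composition, adduct = adduct)
  tibble(
    isomer = c("core", "antennal"),
    mz = c(m, m),
    isobaric = TRUE,
    note = "core and antennal fucose are isobaric at MS1; MS/MS is required to distinguish them"
  )
}

#' Read / write MALDI peak lists
#'
#' Delimited text with columns `mz` and `intensity`.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return Tibble with columns `mz`, `intensity`.
#' @export
read_peak_list <- function(path, delim = "\t") {
  out <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort(paste0("cannot read peak list ", path, ": ",
                                     conditionMessage(e)))
  )
  if (!"mz" %in% names(out)) abort("peak list must have an 'mz' column")
  if (!"intensity" %in% names(out)) out$intensity <- NA_real_
  dplyr::select(out, "mz", "intensity")
}

#' @rdname read_peak_list
#' @param peaks Peak tibble to write.
#' @export
write_peak_list <- function(peaks, path, delim = "\t") {
  if (!"mz" %in% names(peaks)) abort("peak list must have an 'mz' column")
  readr::write_delim(peaks, path, delim = delim)
  invisible(path)
}
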