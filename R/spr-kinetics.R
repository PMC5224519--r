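#' Define a 1:1 Langmuir binding model
#'
#' Pseudo-first-order surface binding: `dR/dt = kon*C*(Rmax - R) - koff*R`,
#' with equilibrium constant `KD = koff/kon`. This is the model behind
#' standard biosensor kinetic analysis of monovalent (or apparent-avidity)
#' interactions; the hexameric-Fc/DC-SIGN interaction, for instance, is
#' summarised by apparent constants of this form.
#'
#' @param kon Association rate constant (M^-1 s^-1), > 0.
#' @param koff Dissociation rate constant (s^-1), >= 0.
#' @param rmax Maximal response (RU), > 0.
#' @return A `langmuir_model` object; `$kd` is `koff/kon` (M).
#' @examples
#' m <- langmuir_model(kon = 6.68e2, koff = 8.39e-4, rmax = 100)
#' m$kd  # 1.26e-6 M
#' @export
langmuir_model <- function(kon, koff, rmax) {
  if (kon <= 0) abort("kon must be positive")
  if (koff < 0) abort("koff must be non-negative")
  if (rmax <= 0) abort("rmax must be positive")
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon),
            class = "langmuir_model")
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param kon Association rate constant (M^-1 s^-1), > 0.
#' @param koff Dissociation rate constant (s^-1).
#' @return `KD = koff / kon` (M).
#' @examples
#' kd_from_rates(6.68e2, 8.39e-4) # 1.26 uM
#' kd_from_rates(3.6e4, 1.58e-4)  # 4.39 nM
#' @export
kd_from_rates <- function(kon, koff) {
  if (any(kon <= 0)) abort("kon must be positive")
  koff / kon
}

#' Define an injection schedule for sensorgram simulation
#'
#' Analyte flows from time 0 and is replaced by buffer at `t_switch`
#' (default 300 s), the layout of a doubling-dilution multichannel SPR
#' experiment.
#'
#' @param concentrations Analyte concentrations (M), distinct and positive;
#'   see [doubling_dilutions()].
#' @param t_switch Buffer-switch time (s).
#' @param t_end End of acquisition (s).
#' @param dt Sampling interval (s).
#' @return An `injection_schedule` object.
#' @export
injection_schedule <- function(concentrations, t_switch = 300, t_end = 600,
                               dt = 1) {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (anyDuplicated(concentrations)) abort("concentrations must be distinct")
  if (!(0 < t_switch && t_switch < t_end)) {
    abort("need 0 < t_switch < t_end")
  }
  if (dt <= 0) abort("sampling interval must be positive")
  structure(list(concentrations = sort(concentrations, decreasing = TRUE),
                 t_switch = t_switch, t_end = t_end, dt = dt),
            class = "injection_schedule")
}

#' Doubling-dilution concentration series
#'
#' @param top Top concentration (M).
#' @param n Number of dilutions.
#' @return `top / 2^(0:(n-1))`.
#' @export
doubling_dilutions <- function(top, n) {
  if (top <= 0 || n < 1) abort("need top > 0 and n >= 1")
  top / 2^(0:(n - 1))
}

# Closed-form 1:1 Langmuir response. Association uses
# R(t) = Req (1 - exp(-kobs t)) with kobs = kon C + koff and
# Req = Rmax kon C / kobs; dissociation decays from the switch-point
# response with rate koff.
langmuir_response <- function(times, conc, kon, koff, rmax, t_switch) {
  n <- max(length(times), length(conc))
  times <- rep_len(times, n)
  kobs <- rep_len(kon * conc + koff, n)
  req <- rep_len(rmax * kon * conc, n) / kobs
  r <- req * (1 - exp(-kobs * pmin(times, t_switch)))
  dis <- times > t_switch
  if (any(dis)) {
    r_sw <- req[dis] * (1 - exp(-kobs[dis] * t_switch))
    r[dis] <- r_sw * exp(-koff * (times[dis] - t_switch))
  }
  r
}

#' Simulate 1:1 Langmuir sensorgrams
#'
#' Generates one association/dissociation curve per concentration from the
#' analytic solution of the 1:1 model, optionally with i.i.d. Gaussian
#' noise.
#'
#' @param model A [langmuir_model()].
#' @param schedule An [injection_schedule()].
#' @param noise_sd Gaussian noise standard deviation (RU); 0 gives the exact
#'   closed form.
#' @param seed Optional integer seed for the noise.
#' @return Tibble with columns `time_s`, `response_RU`, `concentration_M`;
#'   the schedule is attached as the `"schedule"` attribute.
#' @examples
#' m <- langmuir_model(6.68e2, 8.39e-4, 100)
#' sch <- injection_schedule(doubling_dilutions(16 * m$kd, 6))
#' curves <- simulate_sensorgrams(m, sch)
#' @export
simulate_sensorgrams <- function(model, schedule, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "langmuir_model"),
            inherits(schedule, "injection_schedule"))
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  times <- seq(0, schedule$t_end, by = schedule$dt)
  sim <- function() {
    purrr::map_dfr(schedule$concentrations, function(conc) {
      r <- langmuir_response(times, conc, model$kon, model$koff, model$rmax,
                             schedule$t_switch)
      if (noise_sd > 0) r <- r + rnorm(length(r), sd = noise_sd)
      tibble(time_s = times, response_RU = r, concentration_M = conc)
    })
  }
  out <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  attr(out, "schedule") <- schedule
  out
}

#' Globally fit the 1:1 Langmuir model to sensorgrams
#'
#' Least-squares fit of `kon`, `koff`, `Rmax` shared across all
#' concentrations (the standard global-analysis convention for
#' multi-channel data recorded on one surface), by Levenberg-Marquardt on
#' log-transformed parameters so the rates stay positive. `KD` is always
#' derived as fitted `koff/kon`, never fitted independently. A per-curve
#' mode is available for diagnostics.
#'
#' @param sensorgrams Tibble with columns `time_s`, `response_RU`,
#'   `concentration_M` ([simulate_sensorgrams()] or
#'   [read_sensorgram_table()] output).
#' @param t_switch Buffer-switch time (s); taken from the attached schedule
#'   if `NULL`.
#' @param start Optional named list/vector with `kon`, `koff`, `rmax`
#'   initial values; otherwise derived from curve features (dissociation
#'   log-slope seeds `koff`, the plateau seeds `rmax`).
#' @param per_curve If `TRUE`, fit each concentration separately and return
#'   a tibble of per-curve estimates.
#' @return A `langmuir_fit` object (or a tibble in per-curve mode) with
#'   fitted `kon`, `koff`, `rmax`, derived `kd`, per-curve residual RMS and
#'   a convergence flag. Non-convergence is reported in the object, not
#'   thrown.
#' @export
fit_langmuir <- function(sensorgrams, t_switch = NULL, start = NULL,
                         per_curve = FALSE) {
  need <- c("time_s", "response_RU", "concentration_M")
  if (!all(need %in% names(sensorgrams))) {
    abort(paste0("sensorgrams must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(sensorgrams) == 0) abort("no sensorgram data")
  if (all(sensorgrams$response_RU == 0)) {
    abort("all responses are zero; nothing to fit")
  }
  if (is.null(t_switch)) {
    sch <- attr(sensorgrams, "schedule")
    if (is.null(sch)) abort("t_switch not given and no schedule attached")
    t_switch <- sch$t_switch
  }
  concs <- sort(unique(sensorgrams$concentration_M), decreasing = TRUE)
  if (length(concs) == 1 && !per_curve) {
    warn("fitting a single concentration; global analysis normally uses >= 2")
  }
  if (per_curve) {
    return(purrr::map_dfr(concs, function(cc) {
      one <- dplyr::filter(sensorgrams, .data$concentration_M == cc)
      fit <- suppressWarnings(
        fit_langmuir(one, t_switch = t_switch, start = start,
                     per_curve = FALSE)
      )
      tibble(concentration_M = cc, kon = fit$kon, koff = fit$koff,
             rmax = fit$rmax, kd = fit$kd, converged = fit$converged)
    }))
  }

  p0 <- start %||% default_start(sensorgrams, t_switch)
  par0 <- log(c(kon = unname(p0[["kon"]]), koff = max(unname(p0[["koff"]]), 1e-12),
                rmax = unname(p0[["rmax"]])))
  resid_fun <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3])
    pred <- langmuir_response(sensorgrams$time_s, sensorgrams$concentration_M,
                              kon, koff, rmax, t_switch)
    pred - sensorgrams$response_RU
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxiter = 1000, maxfev = 10000
    )
  )
  est <- exp(fit$par)
  pred <- sensorgrams$response_RU + fit$fvec  # fvec = pred - obs at optimum
  per_rms <- tibble(residual = fit$fvec,
                    concentration_M = sensorgrams$concentration_M) |>
    dplyr::group_by(.data$concentration_M) |>
    dplyr::summarise(rms = sqrt(mean(.data$residual^2)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$concentration_M))
  structure(
    list(kon = est[["kon"]], koff = est[["koff"]], rmax = est[["rmax"]],
         kd = est[["koff"]] / est[["kon"]],
         converged = fit$info %in% 1:4, info = fit$info,
         message = fit$message, niter = fit$niter,
         rss = sum(fit$fvec^2), residual_rms = per_rms,
         t_switch = t_switch, n_obs = nrow(sensorgrams),
         n_curves = length(concs), data = as_tibble(sensorgrams)),
    class = "langmuir_fit"
  )
}

# Feature-based initial guess: Rmax just above the largest observed
# response, koff from the log-linear dissociation slope of the
# top-concentration curve, kon from the association half-time.
default_start <- function(sensorgrams, t_switch) {
  top <- max(sensorgrams$concentration_M)
  cur <- dplyr::filter(sensorgrams, .data$concentration_M == top)
  rmax0 <- max(sensorgrams$response_RU) * 1.1
  dis <- dplyr::filter(cur, .data$time_s > t_switch,
                       .data$response_RU > 0.01 * rmax0)
  koff0 <- 1e-3
  if (nrow(dis) >= 3) {
    sl <- unname(coef(lm(log(response_RU) ~ time_s, data = dis))[2])
    if (is.finite(sl) && sl < 0) koff0 <- -sl
  }
  assoc <- dplyr::filter(cur, .data$time_s <= t_switch)
  plateau <- max(assoc$response_RU)
  t_half <- assoc$time_s[which(assoc$response_RU >= plateau / 2)[1]]
  kobs0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1e-2
  kon0 <- max((kobs0 - koff0) / top, 1e-6 / top)
  c(kon = kon0, koff = koff0, rmax = rmax0)
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit (", x$n_curves, " curves, ", x$n_obs,
      " points)\n", sep = "")
  cat(sprintf("  kon  = %.4g M^-1 s^-1\n", x$kon))
  cat(sprintf("  koff = %.4g s^-1\n", x$koff))
  cat(sprintf("  Rmax = %.4g RU\n", x$rmax))
  cat(sprintf("  KD   = %.4g M (koff/kon)\n", x$kd))
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Tidy a Langmuir fit into one row per parameter
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `unit`.
#' @exportS3Method generics::tidy
tidy.langmuir_fit <- function(x, ...) {
  tibble(
    term = c("kon", "koff", "rmax", "kd"),
    estimate = c(x$kon, x$koff, x$rmax, x$kd),
    unit = c("M^-1 s^-1", "s^-1", "RU", "M")
  )
}

#' One-row summary of a Langmuir fit
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @return One-row tibble with estimates, RSS and convergence flag.
#' @exportS3Method generics::glance
glance.langmuir_fit <- function(x, ...) {
  tibble(kon = x$kon, koff = x$koff, rmax = x$rmax, kd = x$kd,
         rss = x$rss, n_obs = x$n_obs, n_curves = x$n_curves,
         converged = x$converged)
}

#' Read / write sensorgram tables
#'
#' Delimited text (tab by default) with columns `time_s`, `response_RU`,
#' `concentration_M`; one row per sample point, one series per
#' concentration. Curves with unequal time grids are kept per curve.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `read_sensorgram_table()`: tibble of curves;
#'   `write_sensorgram_table()`: `path`, invisibly.
#' @export
read_sensorgram_table <- function(path, delim = "\t") {
  out <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort(paste0("cannot read sensorgram table ", path,
                                     ": ", conditionMessage(e)))
  )
  need <- c("time_s", "response_RU", "concentration_M")
  if (nrow(out) == 0 || !all(need %in% names(out))) {
    abort(paste0("sensorgram table must have columns ",
                 paste(need, collapse = ", ")))
  }
  dplyr::select(out, dplyr::all_of(need))
}

#' @rdname read_sensorgram_table
#' @param curves Sensorgram tibble to write.
#' @export
write_sensorgram_table <- function(curves, path, delim = "\t") {
  need <- c("time_s", "response_RU", "concentration_M")
  if (!all(need %in% names(curves))) {
    abort(paste0("sensorgram table must have columns ",
                 paste(need, collapse = ", ")))
  }
  readr::write_delim(curves[, need], path, delim = delim)
  invisible(path)
}
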