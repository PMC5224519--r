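hexafc_model <- function() langmuir_model(kon = 6.68e2, koff = 8.39e-4,
                                          rmax = 100)

test_that("model constructors validate and derive KD consistently", {
  m <- hexafc_model()
  expect_equal(m$kd * m$kon, m$koff, tolerance = 1e-12)
  expect_equal(kd_from_rates(1, 1), 1)
  expect_error(langmuir_model(-1, 1, 100), "kon")
  expect_error(langmuir_model(1, -1, 100), "koff")
  expect_error(kd_from_rates(0, 1), "kon")
  expect_error(injection_schedule(c(1e-6, 1e-6)), "distinct")
  expect_error(injection_schedule(1e-6, t_switch = 700, t_end = 600),
               "t_switch")
})

test_that("simulated responses obey the closed-form limits", {
  m <- hexafc_model()
  sch <- injection_schedule(c(1e-12, m$kd), t_switch = 300, t_end = 400)
  curves <- simulate_sensorgrams(m, sch)
  # C -> 0: response vanishes
  lowest <- dplyr::filter(curves, .data$concentration_M == 1e-12)
  expect_lt(max(abs(lowest$response_RU)), 1e-4)
  # C = KD, t -> infinity: Req = Rmax/2
  t_inf <- 1e7
  r_inf <- glycofc:::langmuir_response(t_inf, m$kd, m$kon, m$koff, m$rmax,
                                       t_switch = 2e7)
  expect_equal(r_inf, m$rmax / 2, tolerance = 1e-9)
  expect_error(simulate_sensorgrams(m, sch, noise_sd = -1), "noise_sd")
})

test_that("the analytic solution matches step-by-step ODE integration", {
  m <- hexafc_model()
  times <- seq(0, 600, by = 10)
  for (mult in c(10, 1, 0.25)) {
    conc <- mult * m$kd
    analytic <- glycofc:::langmuir_response(times, conc, m$kon, m$koff,
                                            m$rmax, t_switch = 300)
    euler <- euler_sensorgram(times, conc, m$kon, m$koff, m$rmax,
                              t_switch = 300)
    expect_lt(max(abs(analytic - euler)) / max(analytic), 1e-3)
    # and an independent adaptive integrator agrees more tightly
    ode <- deSolve::ode(
      y = c(R = 0), times = times,
      func = function(t, y, p) {
        cc <- if (t < 300) conc else 0
        list(m$kon * cc * (m$rmax - y[1]) - m$koff * y[1])
      }, parms = NULL, rtol = 1e-10, atol = 1e-10)
    expect_lt(max(abs(analytic - ode[, "R"])) / max(analytic), 1e-6)
  }
})

test_that("equilibrium response is increasing in C and bounded by Rmax", {
  m <- hexafc_model()
  concs <- m$kd * 2^seq(-4, 6)
  req <- m$rmax * m$kon * concs / (m$kon * concs + m$koff)
  expect_true(all(diff(req) > 0))
  expect_true(all(req < m$rmax))
})

test_that("dissociation is strictly decreasing whenever koff > 0", {
  m <- hexafc_model()
  sch <- injection_schedule(doubling_dilutions(16 * m$kd, 3))
  curves <- simulate_sensorgrams(m, sch)
  dis <- dplyr::filter(curves, .data$time_s > sch$t_switch)
  for (cc in unique(dis$concentration_M)) {
    r <- dis$response_RU[dis$concentration_M == cc]
    expect_true(all(diff(r) < 0))
  }
})

test_that("noiseless global fits recover the generating rates to 0.1%", {
  m <- hexafc_model()
  sch <- injection_schedule(doubling_dilutions(16 * m$kd, 6))
  fit <- fit_langmuir(simulate_sensorgrams(m, sch))
  expect_true(fit$converged)
  expect_lt(abs(fit$kon - m$kon) / m$kon, 1e-3)
  expect_lt(abs(fit$koff - m$koff) / m$koff, 1e-3)
  expect_lt(abs(fit$rmax - m$rmax) / m$rmax, 1e-3)
  expect_equal(fit$kd, fit$koff / fit$kon)
})

test_that("curves simulated without dissociation fit koff at zero", {
  m <- langmuir_model(kon = 1e3, koff = 0, rmax = 100)
  sch <- injection_schedule(doubling_dilutions(1e-5, 4))
  fit <- fit_langmuir(simulate_sensorgrams(m, sch))
  expect_lte(fit$koff, 1e-6)
})

test_that("jointly doubling concentrations and Rmax leaves the rates fixed", {
  m1 <- hexafc_model()
  sch1 <- injection_schedule(doubling_dilutions(16 * m1$kd, 5))
  f1 <- fit_langmuir(simulate_sensorgrams(m1, sch1))
  m2 <- langmuir_model(m1$kon, m1$koff, 2 * m1$rmax)
  sch2 <- injection_schedule(doubling_dilutions(32 * m1$kd, 5))
  f2 <- fit_langmuir(simulate_sensorgrams(m2, sch2))
  expect_equal(f2$kon, f1$kon, tolerance = 1e-6)
  expect_equal(f2$koff, f1$koff, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected and single curves warn", {
  m <- hexafc_model()
  sch <- injection_schedule(m$kd)
  one <- simulate_sensorgrams(m, sch)
  expect_warning(fit_langmuir(one), "single concentration")
  zeros <- dplyr::mutate(one, response_RU = 0)
  expect_error(fit_langmuir(zeros, t_switch = 300), "zero")
  expect_error(fit_langmuir(one[, 1:2], t_switch = 300), "columns")
})

test_that("per-curve mode returns one estimate per concentration", {
  m <- hexafc_model()
  sch <- injection_schedule(doubling_dilutions(16 * m$kd, 3))
  pc <- fit_langmuir(simulate_sensorgrams(m, sch), per_curve = TRUE)
  expect_equal(nrow(pc), 3)
  expect_true(all(abs(pc$koff - m$koff) / m$koff < 1e-3))
})

test_that("tidy and glance summarise the fit in broom style", {
  m <- hexafc_model()
  sch <- injection_schedule(doubling_dilutions(16 * m$kd, 4))
  fit <- fit_langmuir(simulate_sensorgrams(m, sch))
  td <- tidy(fit)
  expect_setequal(td$term, c("kon", "koff", "rmax", "kd"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_output(print(fit), "Langmuir")
})

test_that("sensorgram tables round-trip through delimited text", {
  m <- hexafc_model()
  sch <- injection_schedule(doubling_dilutions(16 * m$kd, 3), dt = 25)
  curves <- simulate_sensorgrams(m, sch)
  f <- tempfile(fileext = ".tsv")
  write_sensorgram_table(curves, f)
  back <- read_sensorgram_table(f)
  expect_equal(back, curves[, c("time_s", "response_RU", "concentration_M")],
               tolerance = 1e-12, ignore_attr = TRUE)
  # unequal per-curve time grids are kept as given
  ragged <- dplyr::bind_rows(
    tibble::tibble(time_s = c(0, 1, 2), response_RU = 1:3,
                   concentration_M = 1e-6),
    tibble::tibble(time_s = c(0, 5), response_RU = 4:5,
                   concentration_M = 2e-6))
  write_sensorgram_table(ragged, f)
  expect_equal(nrow(read_sensorgram_table(f)), 5)

  empty <- tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_sensorgram_table(empty), "column")
  writeLines("time_s\tresponse_RU", empty)
  expect_error(read_sensorgram_table(empty), "column")
})
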