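test_that("power-law fits recover exact data to machine precision", {
  omega <- 2 * pi * 10^seq(-1, log10(50), length.out = 20)
  gs <- 1000 * omega^0.25
  sweep <- frequency_sweep(omega = omega,
                           g_prime = gs * cos(pi / 8),
                           g_doubleprime = gs * sin(pi / 8))
  fit <- fit_power_law(sweep)
  expect_equal(fit$a_f, 1000, tolerance = 1e-12)
  expect_equal(fit$z, 4, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  # frequency-grid invariance: same power law, different grid
  omega2 <- 2 * pi * seq(0.1, 50, length.out = 37)
  gs2 <- 1000 * omega2^0.25
  fit2 <- fit_power_law(frequency_sweep(omega = omega2,
                                        g_prime = gs2 * cos(pi / 8),
                                        g_doubleprime = gs2 * sin(pi / 8)))
  expect_equal(fit2$a_f, fit$a_f, tolerance = 1e-10)
  expect_equal(fit2$z, fit$z, tolerance = 1e-10)

  # constant modulus: zero slope is non-physical
  flat <- frequency_sweep(omega = omega, g_prime = rep(1000, 20),
                          g_doubleprime = rep(400, 20))
  expect_error(fit_power_law(flat), "nonpositive")
})

test_that("noisy power-law fits agree with a natural-scale NLS oracle", {
  set.seed(17)
  omega <- 2 * pi * 10^seq(-1, log10(50), length.out = 25)
  gs <- 1000 * omega^0.25 * rlnorm(25, 0, 0.02)
  sweep <- frequency_sweep(omega = omega, g_prime = gs * cos(pi / 8),
                           g_doubleprime = gs * sin(pi / 8), g_star = gs)
  fit <- fit_power_law(sweep)
  expect_lt(rel_err(fit$a_f, 1000), 0.05)
  expect_lt(rel_err(fit$z, 4), 0.05)
  oracle <- nls_power_law_oracle(omega, gs)
  expect_lt(rel_err(fit$a_f, oracle$a_f), 0.05)
  expect_lt(rel_err(fit$z, oracle$z), 0.05)
})

test_that("sweep attributes at 1 Hz interpolate on the log-log scale", {
  crv <- ref_curves()
  sw <- attributes_from_sweep(crv$sweep)
  # the default grid contains 1 Hz, so the value is tabulated exactly
  expect_equal(unname(sw["g_star_1hz"]), 1000 * (2 * pi)^0.25,
               tolerance = 1e-12)
  expect_equal(unname(sw["tan_delta"]), tan(pi / 8), tolerance = 1e-12)

  # G' = G'' everywhere forces tan(delta) = 1
  omega <- 2 * pi * c(0.5, 1, 2)
  eq <- frequency_sweep(omega = omega, g_prime = c(100, 120, 150),
                        g_doubleprime = c(100, 120, 150))
  expect_equal(unname(attributes_from_sweep(eq)["tan_delta"]), 1)

  # two-point bracket of 1 Hz on a known power law: log-log
  # interpolation reproduces the closed form exactly
  omega_b <- 2 * pi * c(0.5, 2)
  gsb <- 1000 * omega_b^0.25
  br <- frequency_sweep(omega = omega_b, g_prime = gsb * cos(pi / 8),
                        g_doubleprime = gsb * sin(pi / 8))
  expect_equal(unname(attributes_from_sweep(br)["g_star_1hz"]),
               1000 * (2 * pi)^0.25, tolerance = 1e-12)
  out <- frequency_sweep(omega = 2 * pi * c(2, 4, 8),
                         g_prime = c(1, 2, 3) * 100,
                         g_doubleprime = c(1, 2, 3) * 40)
  expect_error(attributes_from_sweep(out), "outside")
})

test_that("Burgers round trips recover the generating parameters", {
  crv <- ref_curves()
  cf <- fit_burgers_creep(crv$curve)
  expect_lt(rel_err(cf$j0, ref_creep$j0), 1e-6)
  expect_lt(rel_err(cf$j1, ref_creep$j1), 1e-6)
  expect_lt(rel_err(cf$lambda, ref_creep$lambda), 1e-6)
  expect_lt(rel_err(cf$eta0, ref_creep$eta0), 1e-6)
  expect_true(cf$converged)

  rf <- fit_burgers_recovery(crv$curve)
  expect_lt(rel_err(rf$j0, ref_recovery$j0), 1e-5)
  expect_lt(rel_err(rf$j1, ref_recovery$j1), 1e-5)
  expect_lt(rel_err(rf$j2, ref_recovery$j2), 1e-5)
  expect_lt(rel_err(rf$lambda1, ref_recovery$lambda1), 1e-5)
  expect_lt(rel_err(rf$lambda2, ref_recovery$lambda2), 1e-5)
  expect_lt(rf$lambda1, rf$lambda2)
})

test_that("limiting and degenerate creep/recovery inputs behave", {
  # purely viscous flow: retarded compliances collapse to the bound
  t <- seq(0, 180, 2)
  curve <- creep_recovery_curve(c(t, seq(182, 540, 2)),
                                c(t / 1e5, rep(180 / 1e5, 180)))
  cf <- fit_burgers_creep(curve)
  expect_lt(rel_err(cf$eta0, 1e5), 1e-4)
  expect_lt(cf$j0, 1e-9)
  expect_lt(cf$j1, 1e-9)

  # one-Kelvin recovery data: the two-element fit nests the one-element
  tau <- seq(2, 360, 2)
  r_one <- 1e-4 + 1.5e-4 * (1 - exp(-tau / 20))
  j <- c(seq(0, 180, 2) / 1e5 + 2.9e-4,
         max(seq(0, 180, 2) / 1e5 + 2.9e-4) - r_one)
  curve2 <- creep_recovery_curve(c(seq(0, 180, 2), 180 + tau), j)
  rf2 <- fit_burgers_recovery(curve2)
  one_elem_sse <- {
    fit1 <- minpack.lm::nls.lm(
      par = log(c(1e-4, 1.5e-4, 20)),
      fn = function(th) {
        p <- exp(th); p[1] + p[2] * (1 - exp(-tau / p[3])) - r_one
      })
    sum(fit1$fvec^2)
  }
  sse2 <- sum((doughnet:::.burgers_recovered(
    tau, rf2$j0, rf2$j1, rf2$j2, rf2$lambda1, rf2$lambda2) - r_one)^2)
  expect_lte(sse2, one_elem_sse + 1e-20)
  expect_gte(rf2$r2, 1 - 1e-10)

  # equal retardation times: the split is unidentifiable but the sum is not
  r_eq <- 1e-4 + 1e-4 * (1 - exp(-tau / 30)) + 5e-5 * (1 - exp(-tau / 30))
  j3 <- c(seq(0, 180, 2) / 1e5 + 2.9e-4,
          max(seq(0, 180, 2) / 1e5 + 2.9e-4) - r_eq)
  rf3 <- fit_burgers_recovery(
    creep_recovery_curve(c(seq(0, 180, 2), 180 + tau), j3))
  expect_lt(rel_err(rf3$j1 + rf3$j2, 1.5e-4), 0.01)
})

test_that("creep fits under noise track a grid-search oracle", {
  errs <- numeric(25)
  oracle_gap <- numeric(25)
  for (s in seq_len(25)) {
    crv <- ref_curves(noise_cv = 0.03, seed = 100 + s)
    cp <- doughnet:::.creep_phase(crv$curve)
    cf <- fit_burgers_creep(crv$curve)
    errs[s] <- rel_err(cf$eta0, ref_creep$eta0)
    oracle_gap[s] <- rel_err(cf$eta0, grid_creep_oracle(cp$t, cp$j)$eta0)
  }
  expect_lte(median(errs), 0.05)
  expect_lte(median(oracle_gap), 0.02)
})

test_that("recovered eta0 error grows monotonically with noise", {
  rmse <- vapply(c(0.01, 0.03, 0.08), function(cv) {
    sqrt(mean(vapply(seq_len(20), function(s) {
      crv <- ref_curves(noise_cv = cv, seed = 500 + s)
      rel_err(fit_burgers_creep(crv$curve)$eta0, ref_creep$eta0)^2
    }, numeric(1))))
  }, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("derived attributes honour their defining identities", {
  crv <- ref_curves()
  fits <- fit_rheology(crv$sweep, crv$curve)
  at <- fits$attributes
  j_max_cf <- with(ref_creep, j0 + j1 * (1 - exp(-180 / lambda)) +
                     180 / eta0)
  j_r_cf <- with(ref_recovery, j0 + j1 * (1 - exp(-360 / lambda1)) +
                   j2 * (1 - exp(-360 / lambda2)))
  expect_equal(at[["j_max"]], j_max_cf, tolerance = 1e-12)
  expect_equal(at[["j_r"]], j_r_cf, tolerance = 1e-12)
  expect_equal(at[["j_el"]], 100 * j_r_cf / j_max_cf, tolerance = 1e-12)
  expect_equal(at[["eta0"]], ref_creep$eta0, tolerance = 1e-6)
  expect_equal(at[["a_f"]], ref_power_law$a_f, tolerance = 1e-10)
  expect_equal(at[["z"]], ref_power_law$z, tolerance = 1e-10)
  expect_equal(at[["g_star"]], 1000 * (2 * pi)^0.25, tolerance = 1e-10)
  expect_equal(at[["tan_delta"]], tan(pi / 8), tolerance = 1e-10)
  expect_lte(at[["j_r"]], at[["j_max"]])
  expect_true(at[["j_el"]] >= 0 && at[["j_el"]] <= 100)

  # textbook ratio: half recovered means J_el = 50%
  t <- seq(0, 180, 2)
  half <- creep_recovery_curve(c(t, seq(182, 540, 2)),
                               c(2e-3 * t / 180,
                                 seq(2e-3, 1e-3, length.out = 180)))
  rp <- doughnet:::.recovery_phase(half)
  expect_equal(100 * rp$recovered[length(rp$recovered)] / rp$j_creep_end,
               50, tolerance = 1e-10)

  # complete recovery: fully elastic sample scores J_el = 100%
  elastic <- creep_recovery_curve(
    c(t, seq(182, 540, 2)),
    c(rep(2e-3, length(t)), 2e-3 - seq(1.9e-3, 2e-3, length.out = 180) + 0),
    creep_end = 180)
  rp2 <- doughnet:::.recovery_phase(elastic)
  jel2 <- 100 * rp2$recovered[length(rp2$recovered)] / rp2$j_creep_end
  expect_equal(jel2, 100, tolerance = 1e-10)
})

test_that("round trips survive CSV serialization", {
  crv <- ref_curves()
  tf <- tempfile(fileext = ".csv"); tc <- tempfile(fileext = ".csv")
  write_sweep_csv(crv$sweep, tf)
  write_creep_csv(crv$curve, tc)
  sweep2 <- read_sweep_csv(tf)
  curve2 <- read_creep_csv(tc)
  expect_equal(sweep2$omega, crv$sweep$omega, tolerance = 1e-9)
  expect_equal(curve2$j, crv$curve$j, tolerance = 1e-12)
  fit <- fit_burgers_creep(curve2)
  expect_lt(rel_err(fit$eta0, ref_creep$eta0), 1e-5)
  unlink(c(tf, tc))
})
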