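# Model fits to rheometer data: power law on the frequency sweep,
# four/five parameter Burgers models on the creep-recovery curve, and the
# eight derived rheological attributes.

.PAR_LOWER <- 1e-12
.PAR_UPPER <- 1e12

.r2 <- function(obs, fit) {
  1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
}

# Bounded Levenberg-Marquardt on a residual function. Parameters are
# optimized on the log scale: all Burgers parameters are positive by
# definition, the decades-spanning magnitudes (1e-4 1/Pa compliances vs
# 1e5 Pa s viscosities) become comparably scaled, and the boundary
# sticking of projected-bound LM near lambda -> 0 cannot occur.
.bounded_lm <- function(start, residual_fn,
                        lower = rep(.PAR_LOWER, length(start)),
                        upper = rep(.PAR_UPPER, length(start))) {
  theta0 <- log(pmin(pmax(start, lower), upper))
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = function(theta) residual_fn(exp(theta)),
    lower = log(lower), upper = log(upper),
    control = nls.lm.control(maxiter = 1000, maxfev = 10000,
                             ftol = 1e-15, ptol = 1e-15))
  list(par = exp(fit$par), converged = fit$info %in% 1:4)
}

#' Fit the power-law model to a frequency sweep
#'
#' Fits `G*(omega) = a_f * omega^(1/z)` by ordinary least squares of
#' `log G*` on `log omega` (multiplicative-error linearization):
#' `a_f = exp(intercept)`, `1/z = slope`. A nonpositive slope (stiffness
#' not increasing with frequency) is rejected as a non-physical network
#' connectivity.
#'
#' @param sweep a [frequency_sweep()] with >= 3 points.
#' @return List of class `power_law_fit`: `a_f` (Pa s^(1/z)), `z` (-),
#'   `r2` (log-log scale).
#' @examples
#' sw <- generate_rheology_curves(list(a_f = 1000, z = 4),
#'   list(j0 = 1e-4, j1 = 2e-4, lambda = 10, eta0 = 1e5),
#'   list(j0 = 1e-4, j1 = 1e-4, j2 = 5e-5, lambda1 = 5, lambda2 = 60))$sweep
#' fit_power_law(sw)
#' @export
fit_power_law <- function(sweep) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  if (length(sweep$omega) < 3) stop("need >= 3 frequency points")
  fit <- lm(log(sweep$g_star) ~ log(sweep$omega))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("nonpositive log-log slope: non-physical network connectivity")
  structure(list(a_f = exp(unname(coef(fit)[1])), z = 1 / slope,
                 r2 = .r2(log(sweep$g_star), fitted(fit))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law: A_f = %.4g Pa s^(1/z), z = %.4g (R2 = %.4f)\n",
              x$a_f, x$z, x$r2))
  invisible(x)
}

#' Complex modulus and loss factor at 1 Hz
#'
#' Reads `G*` and `tan(delta) = G''/G'` at 1 Hz from a frequency sweep,
#' by log-log linear interpolation when 1 Hz is not a grid point.
#'
#' @param sweep a [frequency_sweep()] whose frequency range brackets 1 Hz.
#' @return Named vector `c(g_star_1hz, tan_delta)`.
#' @export
attributes_from_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  target <- 2 * pi   # omega at 1 Hz
  if (target < min(sweep$omega) || target > max(sweep$omega))
    stop("1 Hz lies outside the sampled frequency range")
  interp <- function(y) {
    exp(approx(log(sweep$omega), log(y), xout = log(target))$y)
  }
  gp <- interp(sweep$g_prime)
  gpp <- interp(sweep$g_doubleprime)
  c(g_star_1hz = interp(sweep$g_star), tan_delta = gpp / gp)
}

.creep_phase <- function(curve) {
  sel <- curve$t <= curve$creep_end
  list(t = curve$t[sel], j = curve$j[sel])
}

.recovery_phase <- function(curve) {
  sel <- curve$t > curve$creep_end
  cp <- .creep_phase(curve)
  if (length(cp$j) == 0) stop("curve holds no creep phase")
  j_end <- cp$j[length(cp$j)]
  list(tau = curve$t[sel] - curve$creep_end,
       recovered = j_end - curve$j[sel],
       j_creep_end = j_end)
}

#' Fit the four-parameter Burgers model to the creep phase
#'
#' Fits `J(t) = j0 + j1*(1 - exp(-t/lambda)) + t/eta0` by bounded
#' nonlinear least squares (Levenberg-Marquardt) with deterministic
#' initialization: `j0` = first compliance sample, `eta0` = inverse
#' terminal slope over the last 20% of the creep phase, `j1` =
#' `J_max - j0 - t_end/eta0`, `lambda` = `t_end/5`. All parameters are
#' bounded to (1e-12, 1e12).
#'
#' @param curve a [creep_recovery_curve()] with >= 8 creep-phase points.
#' @return List of class `burgers_creep_fit`: `j0`, `j1` (1/Pa), `lambda`
#'   (s), `eta0` (Pa s), `r2`, `converged`.
#' @export
fit_burgers_creep <- function(curve) {
  stopifnot(inherits(curve, "creep_recovery_curve"))
  cp <- .creep_phase(curve)
  if (length(cp$t) < 8) stop("need >= 8 points in the creep phase")
  t <- cp$t; j <- cp$j
  t_end <- t[length(t)]
  tail_sel <- t >= 0.8 * t_end
  slope <- coef(lm(j[tail_sel] ~ t[tail_sel]))[2]
  eta0_0 <- if (is.finite(slope) && slope > 0) 1 / slope else .PAR_UPPER / 10
  j0_0 <- max(j[1], .PAR_LOWER)
  j1_0 <- max(j[length(j)] - j0_0 - t_end / eta0_0, .PAR_LOWER)
  start <- c(j0 = j0_0, j1 = j1_0, lambda = t_end / 5, eta0 = eta0_0)

  fit <- .bounded_lm(start, function(p)
    .burgers_creep_j(t, p[1], p[2], p[3], p[4]) - j)
  p <- as.list(fit$par)
  structure(list(j0 = p$j0, j1 = p$j1, lambda = p$lambda, eta0 = p$eta0,
                 r2 = .r2(j, .burgers_creep_j(t, p$j0, p$j1, p$lambda,
                                              p$eta0)),
                 converged = fit$converged),
            class = "burgers_creep_fit")
}

#' @export
print.burgers_creep_fit <- function(x, ...) {
  cat(sprintf(
    "Burgers creep: J0 = %.4g, J1 = %.4g 1/Pa, lambda = %.4g s, eta0 = %.4g Pa s (R2 = %.5f)\n",
    x$j0, x$j1, x$lambda, x$eta0, x$r2))
  invisible(x)
}

#' Fit the five-parameter Burgers model to the recovery phase
#'
#' Models the *recovered* compliance `R(tau) = J(creep end) -
#' J(creep end + tau)` as `j0 + j1*(1 - exp(-tau/lambda1)) +
#' j2*(1 - exp(-tau/lambda2))` (instantaneous elastic recovery plus two
#' Kelvin elements). Modelling the recovered rather than the residual
#' compliance keeps the relative elastic part `j_r/j_max*100` equal to
#' 100% for a fully elastic sample. Retardation times are ordered
#' `lambda1 < lambda2` by a post-hoc swap.
#'
#' @param curve a [creep_recovery_curve()] with >= 10 recovery-phase
#'   points.
#' @return List of class `burgers_recovery_fit`: `j0`, `j1`, `j2` (1/Pa),
#'   `lambda1`, `lambda2` (s), `r2`, `converged`.
#' @export
fit_burgers_recovery <- function(curve) {
  stopifnot(inherits(curve, "creep_recovery_curve"))
  rp <- .recovery_phase(curve)
  if (length(rp$tau) < 10) stop("need >= 10 points in the recovery phase")
  tau <- rp$tau; r <- rp$recovered
  tau_end <- tau[length(tau)]
  j0_0 <- max(r[1], .PAR_LOWER)
  half <- max((r[length(r)] - j0_0) / 2, .PAR_LOWER)
  start <- c(j0 = j0_0, j1 = half, j2 = half,
             lambda1 = tau_end / 20, lambda2 = tau_end / 2)

  fit <- .bounded_lm(start, function(p)
    .burgers_recovered(tau, p[1], p[2], p[3], p[4], p[5]) - r)
  p <- as.list(fit$par)
  if (p$lambda1 > p$lambda2) {
    p[c("lambda1", "lambda2")] <- p[c("lambda2", "lambda1")]
    p[c("j1", "j2")] <- p[c("j2", "j1")]
  }
  structure(list(j0 = p$j0, j1 = p$j1, j2 = p$j2,
                 lambda1 = p$lambda1, lambda2 = p$lambda2,
                 r2 = .r2(r, .burgers_recovered(tau, p$j0, p$j1, p$j2,
                                                p$lambda1, p$lambda2)),
                 converged = fit$converged),
            class = "burgers_recovery_fit")
}

#' @export
print.burgers_recovery_fit <- function(x, ...) {
  cat(sprintf(
    "Burgers recovery: J0 = %.4g, J1 = %.4g, J2 = %.4g 1/Pa, lambda = %.4g / %.4g s (R2 = %.5f)\n",
    x$j0, x$j1, x$j2, x$lambda1, x$lambda2, x$r2))
  invisible(x)
}

#' Derive the eight retained rheological attributes
#'
#' Combines the curve and its fits into the eight attributes: `j_max` =
#' measured compliance at the end of the creep phase; `j_r` = recovered
#' compliance at the end of the recovery phase; `j_el` =
#' `j_r/j_max*100` (%); `eta0` from the creep fit; `a_f` and `z` from the
#' power-law fit; `g_star` and `tan_delta` at 1 Hz from the sweep.
#'
#' @param curve a [creep_recovery_curve()].
#' @param creep_fit a [fit_burgers_creep()] result.
#' @param recovery_fit a [fit_burgers_recovery()] result (used for
#'   completeness checks; `j_r` is read from the data).
#' @param sweep_fit a [fit_power_law()] result.
#' @param sweep the [frequency_sweep()].
#' @return A [rheo_attributes()] vector.
#' @export
derive_attributes <- function(curve, creep_fit, recovery_fit, sweep_fit,
                              sweep) {
  stopifnot(inherits(curve, "creep_recovery_curve"),
            inherits(creep_fit, "burgers_creep_fit"),
            inherits(recovery_fit, "burgers_recovery_fit"),
            inherits(sweep_fit, "power_law_fit"),
            inherits(sweep, "frequency_sweep"))
  rp <- .recovery_phase(curve)
  if (length(rp$tau) == 0) stop("curve holds no recovery phase")
  j_max <- rp$j_creep_end
  j_r <- max(rp$recovered[length(rp$recovered)], 0)
  sw <- attributes_from_sweep(sweep)
  rheo_attributes(
    j_max = j_max, j_r = j_r, j_el = 100 * j_r / j_max,
    eta0 = creep_fit$eta0,
    g_star = unname(sw["g_star_1hz"]),
    tan_delta = unname(sw["tan_delta"]),
    a_f = sweep_fit$a_f, z = sweep_fit$z
  )
}

#' Fit all rheological models to one sample
#'
#' Convenience wrapper running [fit_power_law()], [fit_burgers_creep()],
#' [fit_burgers_recovery()] and [derive_attributes()].
#'
#' @param sweep a [frequency_sweep()].
#' @param curve a [creep_recovery_curve()].
#' @return List of class `rheology_fits` with `power_law`, `creep`,
#'   `recovery`, `attributes`.
#' @export
fit_rheology <- function(sweep, curve) {
  pl <- fit_power_law(sweep)
  cf <- fit_burgers_creep(curve)
  rf <- fit_burgers_recovery(curve)
  structure(list(power_law = pl, creep = cf, recovery = rf,
                 attributes = derive_attributes(curve, cf, rf, pl, sweep)),
            class = "rheology_fits")
}

#' @export
print.rheology_fits <- function(x, ...) {
  print(x$power_law); print(x$creep); print(x$recovery)
  a <- x$attributes
  cat(sprintf(
    "attributes: J_max = %.4g, J_r = %.4g 1/Pa, J_el = %.2f%%, G* = %.4g Pa, tan(delta) = %.3f\n",
    a[["j_max"]], a[["j_r"]], a[["j_el"]], a[["g_star"]], a[["tan_delta"]]))
  invisible(x)
}
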