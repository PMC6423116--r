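# Rheometer curve containers and the closed-form curve generator.

#' Rheometer test protocol
#'
#' Protocol constants for the two shear tests: creep-recovery at constant
#' stress (default 250 Pa for 180 s, recovery for a further 360 s) and an
#' oscillatory frequency sweep (0.1-50 Hz within the linear viscoelastic
#' region, 0.1% strain).
#'
#' @param creep_end end of the creep phase, s.
#' @param recovery_duration duration of the recovery phase, s.
#' @param stress applied shear stress, Pa.
#' @param freq_range frequency sweep range, Hz.
#' @param n_freq number of log-spaced sweep frequencies (1 Hz is always
#'   included).
#' @param dt sampling interval of the creep-recovery curve, s.
#' @param strain_percent oscillatory strain amplitude, % (metadata).
#' @return List of class `rheology_protocol`.
#' @export
rheology_protocol <- function(creep_end = 180, recovery_duration = 360,
                              stress = 250, freq_range = c(0.1, 50),
                              n_freq = 25, dt = 2, strain_percent = 0.1) {
  stopifnot(creep_end > 0, recovery_duration > 0, stress > 0,
            length(freq_range) == 2, all(freq_range > 0), dt > 0)
  structure(list(creep_end = creep_end,
                 recovery_duration = recovery_duration,
                 recovery_end = creep_end + recovery_duration,
                 stress = stress, freq_range = freq_range,
                 n_freq = n_freq, dt = dt,
                 strain_percent = strain_percent),
            class = "rheology_protocol")
}

#' Frequency sweep container
#'
#' Holds an oscillatory frequency sweep. Supply either `frequency_hz` or
#' the angular frequency `omega` (rad/s, `omega = 2*pi*frequency_hz`).
#' If `g_star` is omitted it is computed as `sqrt(g_prime^2 +
#' g_doubleprime^2)`; if all three are supplied their consistency is
#' checked to 1%.
#'
#' @param frequency_hz,omega frequency grid (strictly increasing, > 0).
#' @param g_prime storage modulus G', Pa.
#' @param g_doubleprime loss modulus G'', Pa.
#' @param g_star complex modulus magnitude |G*|, Pa (optional).
#' @return List of class `frequency_sweep` with `omega`, `g_prime`,
#'   `g_doubleprime`, `g_star`.
#' @export
frequency_sweep <- function(frequency_hz = NULL, omega = NULL,
                            g_prime, g_doubleprime, g_star = NULL) {
  if (is.null(omega)) {
    if (is.null(frequency_hz)) stop("supply frequency_hz or omega")
    omega <- 2 * pi * frequency_hz
  }
  if (any(omega <= 0) || any(diff(omega) <= 0))
    stop("omega must be strictly increasing and > 0")
  if (any(g_prime <= 0) || any(g_doubleprime <= 0))
    stop("moduli must be > 0")
  mag <- sqrt(g_prime^2 + g_doubleprime^2)
  if (is.null(g_star)) {
    g_star <- mag
  } else if (any(abs(g_star - mag) / mag > 0.01)) {
    stop("|G*|^2 != G'^2 + G''^2 within 1%")
  }
  structure(list(omega = omega, g_prime = g_prime,
                 g_doubleprime = g_doubleprime, g_star = g_star),
            class = "frequency_sweep")
}

#' Creep-recovery curve container
#'
#' @param t time, s (strictly increasing from the start of the creep
#'   phase).
#' @param j measured compliance J(t), 1/Pa (>= 0).
#' @param creep_end end of the creep phase, s (default 180).
#' @param recovery_end end of the recovery phase, s (default 540 = 180 s
#'   creep + 360 s recovery).
#' @param stress applied shear stress, Pa (default 250).
#' @return List of class `creep_recovery_curve`.
#' @export
creep_recovery_curve <- function(t, j, creep_end = 180, recovery_end = 540,
                                 stress = 250) {
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(j < 0)) stop("compliance must be >= 0")
  if (length(t) != length(j)) stop("t and j must have equal length")
  structure(list(t = t, j = j, creep_end = creep_end,
                 recovery_end = recovery_end, stress = stress),
            class = "creep_recovery_curve")
}

# Closed-form model values --------------------------------------------------

.power_law_gstar <- function(omega, a_f, z) a_f * omega^(1 / z)

.burgers_creep_j <- function(t, j0, j1, lambda, eta0) {
  j0 + j1 * (1 - exp(-t / lambda)) + t / eta0
}

# Recovered compliance tau seconds into the recovery phase.
.burgers_recovered <- function(tau, j0, j1, j2, lambda1, lambda2) {
  j0 + j1 * (1 - exp(-tau / lambda1)) + j2 * (1 - exp(-tau / lambda2))
}

#' Generate synthetic rheometer curves
#'
#' Builds a frequency sweep and a creep-recovery curve from closed-form
#' model parameters, optionally perturbed by multiplicative lognormal
#' noise (mean 1, coefficient of variation `noise_cv`).
#'
#' The sweep follows the power law `G*(omega) = a_f * omega^(1/z)` with a
#' frequency-independent phase angle `delta = pi/(2 z)` (the constant
#' phase a power-law relaxation implies), so `G' = G* cos(delta)` and
#' `G'' = G* sin(delta)`. One noise factor per frequency scales all three
#' moduli, preserving their consistency. The creep phase follows the
#' four-parameter Burgers compliance; the recovery phase is the maximal
#' creep compliance minus the five-parameter (two Kelvin element)
#' recovered compliance.
#'
#' @param power_law list with `a_f` (Pa s^(1/z)) and `z` (-).
#' @param creep list with `j0`, `j1` (1/Pa), `lambda` (s), `eta0` (Pa s).
#' @param recovery list with `j0`, `j1`, `j2` (1/Pa), `lambda1`,
#'   `lambda2` (s).
#' @param protocol a [rheology_protocol()].
#' @param noise_cv lognormal noise CV (>= 0).
#' @param seed integer seed.
#' @return List with elements `sweep` ([frequency_sweep()]) and `curve`
#'   ([creep_recovery_curve()]).
#' @examples
#' crv <- generate_rheology_curves(
#'   power_law = list(a_f = 1000, z = 4),
#'   creep = list(j0 = 1e-4, j1 = 2e-4, lambda = 10, eta0 = 1e5),
#'   recovery = list(j0 = 1e-4, j1 = 1.2e-4, j2 = 6e-5,
#'                   lambda1 = 5, lambda2 = 60))
#' @export
generate_rheology_curves <- function(power_law, creep, recovery,
                                     protocol = rheology_protocol(),
                                     noise_cv = 0, seed = 1) {
  pars <- c(unlist(power_law), unlist(creep), unlist(recovery))
  if (any(pars <= 0)) stop("all model parameters must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2)); meanlog <- -sdlog^2 / 2
  ln <- function(n) if (noise_cv > 0) rlnorm(n, meanlog, sdlog) else rep(1, n)

  f <- sort(unique(c(10^seq(log10(protocol$freq_range[1]),
                            log10(protocol$freq_range[2]),
                            length.out = protocol$n_freq), 1)))
  omega <- 2 * pi * f
  gstar <- .power_law_gstar(omega, power_law$a_f, power_law$z) * ln(length(f))
  delta <- pi / (2 * power_law$z)
  sweep <- frequency_sweep(omega = omega,
                           g_prime = gstar * cos(delta),
                           g_doubleprime = gstar * sin(delta),
                           g_star = gstar)

  t_creep <- seq(0, protocol$creep_end, by = protocol$dt)
  j_creep <- .burgers_creep_j(t_creep, creep$j0, creep$j1, creep$lambda,
                              creep$eta0)
  j_max <- j_creep[length(j_creep)]
  tau <- seq(protocol$dt, protocol$recovery_duration, by = protocol$dt)
  j_rec <- j_max - .burgers_recovered(tau, recovery$j0, recovery$j1,
                                      recovery$j2, recovery$lambda1,
                                      recovery$lambda2)
  if (any(j_rec < 0))
    stop("recovery parameters recover more than the maximal compliance")
  j <- c(j_creep, j_rec) * ln(length(j_creep) + length(tau))
  curve <- creep_recovery_curve(c(t_creep, protocol$creep_end + tau), j,
                                creep_end = protocol$creep_end,
                                recovery_end = protocol$recovery_end,
                                stress = protocol$stress)
  list(sweep = sweep, curve = curve)
}
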