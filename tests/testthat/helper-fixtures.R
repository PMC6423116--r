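# Shared fixture builders and independent oracles.

# Geometric binary fixtures -------------------------------------------------

bar_image <- function(nrow = 64, ncol = 128, rows = 30:32, cols = 10:109) {
  m <- matrix(0L, nrow, ncol)
  m[rows, cols] <- 1L
  m
}

cross_image <- function(n = 64) {
  m <- matrix(0L, n, n)
  mid <- (n %/% 2 - 1):(n %/% 2 + 1)
  m[mid, 10:(n - 10)] <- 1L
  m[10:(n - 10), mid] <- 1L
  m
}

annulus_image <- function(n = 64, r_in = 18, r_out = 24) {
  xy <- expand.grid(i = seq_len(n), j = seq_len(n))
  r <- sqrt((xy$i - (n + 1) / 2)^2 + (xy$j - (n + 1) / 2)^2)
  matrix(as.integer(r >= r_in & r <= r_out), n, n)
}

# Reference Burgers / power-law parameter sets ------------------------------

ref_power_law <- list(a_f = 1000, z = 4)
ref_creep <- list(j0 = 1e-4, j1 = 2e-4, lambda = 10, eta0 = 1e5)
ref_recovery <- list(j0 = 1e-4, j1 = 1.2e-4, j2 = 6e-5,
                     lambda1 = 5, lambda2 = 60)

ref_curves <- function(noise_cv = 0, seed = 1) {
  generate_rheology_curves(ref_power_law, ref_creep, ref_recovery,
                           noise_cv = noise_cv, seed = seed)
}

rel_err <- function(est, truth) abs(est / truth - 1)

# Independent oracles -------------------------------------------------------

# Exhaustive gliding-box lacunarity at a single box size, by direct double
# loop over every fully-inside box position.
brute_force_lacunarity <- function(mask, r) {
  n1 <- nrow(mask) - r + 1L
  n2 <- ncol(mask) - r + 1L
  s <- numeric(n1 * n2)
  k <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    k <- k + 1L
    s[k] <- sum(mask[i:(i + r - 1L), j:(j + r - 1L)])
  }
  mu <- mean(s)
  if (mu == 0) return(0)
  mean((s - mu)^2) / mu^2
}

# Natural-scale nonlinear least squares for the power law (independent of
# the package's log-log linearization).
nls_power_law_oracle <- function(omega, gstar) {
  obj <- function(p) sum((exp(p[1]) * omega^p[2] - gstar)^2)
  fit <- optim(c(log(mean(gstar)), 0.2), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(a_f = exp(fit$par[1]), z = 1 / fit$par[2])
}

# Coarse grid search over lambda with a linear solve for the remaining
# creep parameters (the model is linear in j0, j1, 1/eta0 given lambda),
# then a Nelder-Mead polish. Independent of Levenberg-Marquardt.
grid_creep_oracle <- function(t, j) {
  best <- NULL
  for (lambda in 10^seq(log10(0.5), log10(100), length.out = 60)) {
    X <- cbind(1, 1 - exp(-t / lambda), t)
    beta <- qr.solve(X, j)
    sse <- sum((drop(X %*% beta) - j)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(lambda = lambda, beta = beta, sse = sse)
  }
  obj <- function(p) {
    sum((p[1] + p[2] * (1 - exp(-t / exp(p[3]))) + t * p[4] - j)^2)
  }
  start <- c(best$beta[1], best$beta[2], log(best$lambda), best$beta[3])
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-15))
  list(j0 = fit$par[1], j1 = fit$par[2], lambda = exp(fit$par[3]),
       eta0 = 1 / fit$par[4])
}
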