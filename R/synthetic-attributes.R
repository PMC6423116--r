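#' Generate a synthetic attribute table for one archetype
#'
#' Draws `n` samples of the five microstructural attributes for a given
#' gluten network archetype. Each attribute equals the standard-dough
#' value multiplied by a direction-dependent factor (see
#' [direction_factors()]) and by lognormal noise with coefficient of
#' variation `noise_cv` (mean 1). The lacunarity is clamped into the
#' archetype's range afterwards so generated labels stay consistent with
#' the lacunarity-based classifier.
#'
#' @param archetype an [archetype_spec()] or a network type name.
#' @param standard standard-dough attributes ([micro_attributes()];
#'   default [standard_dough_attributes()]). All values must be > 0.
#' @param n number of samples (>= 1).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (>= 0).
#' @param seed integer seed; the draw is fully reproducible.
#' @param factors arrow-to-factor mapping, see [direction_factors()].
#' @return Data frame with columns `pw`, `br`, `apl`, `ly`, `epr`,
#'   `label`, `seed` (one row per sample).
#' @examples
#' generate_attribute_table("rigid", n = 3, noise_cv = 0.1, seed = 1)
#' @export
generate_attribute_table <- function(archetype,
                                     standard = standard_dough_attributes(),
                                     n = 1, noise_cv = 0, seed = 1,
                                     factors = direction_factors()) {
  if (is.character(archetype)) archetype <- archetype_spec(archetype)
  stopifnot(inherits(archetype, "archetype_spec"))
  standard <- as_micro_attributes(standard)
  if (any(standard <= 0)) stop("standard attributes must all be > 0")
  if (n < 1) stop("n must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")

  dirs <- archetype$attribute_directions          # keyed br,pw,apl,epr,ly
  fac  <- factors[dirs[MICRO_NAMES]]
  mu   <- unclass(standard) * unname(fac)

  sdlog   <- sqrt(log(1 + noise_cv^2))
  meanlog <- -sdlog^2 / 2                          # unit-mean noise
  set.seed(seed)
  noise <- matrix(rlnorm(n * 5L, meanlog, sdlog), nrow = n, ncol = 5L)
  x <- sweep(noise, 2L, mu, `*`)
  colnames(x) <- MICRO_NAMES
  x[, "ly"] <- .clamp_ly(x[, "ly"], archetype$lacunarity_range)

  out <- as.data.frame(x)
  out$label <- archetype$network_type
  out$seed  <- seed
  out
}

#' Generate a linked microstructure-rheology dataset
#'
#' Builds a dataset over all six network archetypes in which the
#' rheological responses are generated *through the shipped prediction
#' equations*: the five attributes are drawn per archetype (lognormal
#' scatter `x_noise_cv` around the direction-scaled standard), each
#' transformed response (log10, reciprocal or identity scale) is the exact
#' linear combination given by [prediction_equations()], Gaussian noise
#' with standard deviation `noise_cv` times the across-sample SD of the
#' noiseless transformed response is added, and the inverse transform maps
#' back to the natural scale. Refitting a PLS model on the noiseless
#' output therefore recovers the shipped coefficients exactly.
#'
#' @param standard standard-dough attributes (> 0).
#' @param n_per_type samples per archetype (>= 2).
#' @param noise_cv relative Gaussian noise on the transformed responses
#'   (0 gives an exact linear dataset).
#' @param seed integer seed.
#' @param x_noise_cv lognormal CV of the attribute scatter (default 0.1).
#' @return Data frame with the five predictors, natural-scale responses
#'   (`j_max`, `j_r`, `j_el`, `eta0`, `g_star`, `tan_delta`, `a_f`, `z`),
#'   `label` and `seed`.
#' @examples
#' d <- generate_linked_dataset(n_per_type = 3, noise_cv = 0, seed = 1)
#' head(d)
#' @export
generate_linked_dataset <- function(standard = standard_dough_attributes(),
                                    n_per_type = 4, noise_cv = 0, seed = 1,
                                    x_noise_cv = 0.1) {
  if (n_per_type < 2) stop("n_per_type must be >= 2")
  xs <- lapply(seq_along(NETWORK_TYPES), function(k) {
    generate_attribute_table(NETWORK_TYPES[k], standard, n = n_per_type,
                             noise_cv = x_noise_cv, seed = seed * 131L + k)
  })
  x <- do.call(rbind, xs)

  eqs <- prediction_equations()
  set.seed(seed * 131L + 7919L)
  for (eq in eqs) {
    eta <- as.matrix(x[MICRO_NAMES]) %*% eq$coefficients + eq$intercept
    eta <- drop(eta)
    if (noise_cv > 0) {
      eta <- eta + rnorm(length(eta), 0, noise_cv * sd(eta))
    }
    x[[eq$response]] <- inverse_transform_values(eta, eq$transform)
  }
  rownames(x) <- NULL
  x[c(MICRO_NAMES, RHEO_NAMES, "label", "seed")]
}
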