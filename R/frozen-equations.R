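# Published PLS prediction equations linking the five microstructural
# attributes to each (transformed) rheological response. Coefficients are
# on the original predictor scales (pw um, br 1/um^2, apl um, ly -,
# epr 1/um^2). `n_factors`, `vip_above_0.8` and `r2y_published` are
# documentation of the source models, not used in evaluation.
.FROZEN_EQUATIONS <- list(
  list(response = "j_max", transform = "log10",
       coefficients = c(pw = 1.598, br = -48.694, apl = 0.016,
                        ly = -9.188, epr = 52.705),
       intercept = -4.874, n_factors = 4L,
       vip_above_0.8 = c("apl", "ly"), r2y_published = 89.65),
  list(response = "j_r", transform = "log10",
       coefficients = c(pw = 0.950, br = -29.975, apl = 0.005,
                        ly = -6.651, epr = 3.072),
       intercept = -2.905, n_factors = 3L,
       vip_above_0.8 = c("apl", "ly"), r2y_published = 81.56),
  list(response = "j_el", transform = "identity",
       coefficients = c(pw = -33.843, br = 689.778, apl = -0.265,
                        ly = 72.428, epr = -1591.011),
       intercept = 132.938, n_factors = 4L,
       vip_above_0.8 = c("pw", "br", "apl", "ly", "epr"),
       r2y_published = 71.85),
  list(response = "eta0", transform = "log10",
       coefficients = c(pw = -1.567, br = 57.529, apl = -0.018,
                        ly = 11.776, epr = -54.449),
       intercept = 6.519, n_factors = 4L,
       vip_above_0.8 = c("apl", "ly"), r2y_published = 89.68),
  list(response = "g_star", transform = "reciprocal",
       coefficients = c(pw = 9.275e-5, br = -2.446e-3, apl = 8.503e-7,
                        ly = -4.547e-4, epr = 3.391e-3),
       intercept = -8.588e-5, n_factors = 5L,
       vip_above_0.8 = c("br", "ly"), r2y_published = 84.26),
  list(response = "tan_delta", transform = "identity",
       coefficients = c(pw = 0.151, br = -4.067, apl = 7.868e-4,
                        ly = -1.010, epr = 1.501),
       intercept = 0.377, n_factors = 3L,
       vip_above_0.8 = c("apl", "ly"), r2y_published = 84.83),
  list(response = "a_f", transform = "reciprocal",
       coefficients = c(pw = 9.161e-5, br = -2.491e-3, apl = 8.597e-7,
                        ly = -4.586e-4, epr = 3.489e-3),
       intercept = -8.525e-5, n_factors = 5L,
       vip_above_0.8 = c("pw", "br", "ly"), r2y_published = 83.81),
  list(response = "z", transform = "identity",
       coefficients = c(pw = 2.222, br = 81.507, apl = -5.997e-3,
                        ly = 13.389, epr = -29.568),
       intercept = -5.274, n_factors = 4L,
       vip_above_0.8 = c("apl", "ly"), r2y_published = 83.26)
)

#' Frozen rheology prediction equations
#'
#' The eight published prediction equations, one per rheological
#' response. Each equation is a linear combination of the five
#' microstructural attributes on a transformed response scale (log10 for
#' `j_max`, `j_r`, `eta0`; reciprocal for `g_star`, `a_f`; identity for
#' `j_el`, `tan_delta`, `z`). A machine-readable copy is shipped at
#' `system.file("extdata", "prediction_equations.json", package =
#' "doughnet")`.
#'
#' @param response optional response name; if given, the single matching
#'   equation is returned.
#' @return A named list of `frozen_equation` objects (or a single one).
#'   Each holds `response`, `transform`, `coefficients` (named by
#'   predictor), `intercept`, `n_factors`, `vip_above_0.8` and
#'   `r2y_published`.
#' @examples
#' prediction_equations("j_max")$intercept
#' @export
prediction_equations <- function(response = NULL) {
  eqs <- lapply(.FROZEN_EQUATIONS, function(e) {
    class(e) <- "frozen_equation"
    e
  })
  names(eqs) <- vapply(eqs, `[[`, "", "response")
  if (is.null(response)) return(eqs)
  if (!response %in% names(eqs))
    stop("unknown response: ", response, " (expected one of ",
         paste(names(eqs), collapse = ", "), ")")
  eqs[[response]]
}

#' @export
print.frozen_equation <- function(x, ...) {
  lhs <- switch(x$transform,
                log10 = sprintf("log10(%s)", x$response),
                reciprocal = sprintf("1/%s", x$response),
                x$response)
  terms <- sprintf("%+.6g*%s", x$coefficients, names(x$coefficients))
  cat(lhs, "=", paste(terms, collapse = " "),
      sprintf("%+.6g", x$intercept), "\n")
  cat(sprintf("  published: %d PLS factors, R2Y = %.2f%%, VIP>0.8: %s\n",
              x$n_factors, x$r2y_published,
              paste(x$vip_above_0.8, collapse = ", ")))
  invisible(x)
}

#' Predict one rheological response from microstructure
#'
#' Evaluates a frozen prediction equation at a sample's five
#' microstructural attributes and back-transforms to the natural scale.
#' Reciprocal responses whose transformed prediction is <= 0 are flagged
#' as non-physical (the linear models admit such outputs for extreme
#' inputs) rather than raising an error.
#'
#' @param micro a [micro_attributes()] vector (or coercible).
#' @param equation a `frozen_equation` or a response name.
#' @return List of class `prediction_result`: `response`, `transformed`,
#'   `natural`, `non_physical` flag and the echoed `inputs`.
#' @examples
#' predict_rheology(standard_dough_attributes(), "j_max")
#' @export
predict_rheology <- function(micro, equation) {
  micro <- as_micro_attributes(micro)
  if (is.character(equation)) equation <- prediction_equations(equation)
  stopifnot(inherits(equation, "frozen_equation"))
  eta <- sum(equation$coefficients[MICRO_NAMES] * unclass(micro)[MICRO_NAMES]) +
    equation$intercept
  natural <- inverse_transform_values(eta, equation$transform)
  structure(list(
    response     = equation$response,
    transformed  = eta,
    natural      = natural,
    non_physical = equation$transform == "reciprocal" && eta <= 0,
    inputs       = unclass(micro)
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s: %.6g (transformed %.6g)%s\n", x$response, x$natural,
              x$transformed,
              if (x$non_physical) "  [non-physical: 1/y <= 0]" else ""))
  invisible(x)
}

#' Predict all eight rheological responses from microstructure
#'
#' Applies every frozen equation to one sample. Natural-scale consistency
#' (`j_r <= j_max`) is not enforced; a violation is reported through the
#' `consistency_warning` attribute since the independent per-response
#' models can disagree for unusual inputs.
#'
#' @inheritParams predict_rheology
#' @return Named list of [predict_rheology()] results, one per response,
#'   with attribute `consistency_warning`.
#' @export
predict_all_rheology <- function(micro) {
  micro <- as_micro_attributes(micro)
  out <- lapply(prediction_equations(), function(eq)
    predict_rheology(micro, eq))
  warn <- character()
  if (out$j_r$natural > out$j_max$natural)
    warn <- c(warn, "predicted j_r exceeds predicted j_max")
  attr(out, "consistency_warning") <- warn
  out
}

#' Relative prediction error summary
#'
#' Per-response relative standard error of natural-scale predictions,
#' RSE% = 100 * sqrt(mean(((predicted - observed)/observed)^2)), grouped
#' by response transform class (identity / logarithmic / reciprocal).
#'
#' @param predicted,observed paired natural-scale value vectors.
#' @param response response name (determines the transform group).
#' @return Data frame with `response`, `transform_group`, `n`,
#'   `rse_percent`.
#' @export
prediction_error_report <- function(predicted, observed, response) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  transforms <- response_transforms()
  if (!response %in% names(transforms)) stop("unknown response: ", response)
  rse <- 100 * sqrt(mean(((predicted - observed) / observed)^2))
  data.frame(response = response,
             transform_group = transforms[[response]],
             n = length(predicted),
             rse_percent = rse,
             row.names = NULL)
}
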