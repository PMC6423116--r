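# Pairwise correlation analysis with linear and exponential candidate
# models, and a PCA wrapper.

#' Fit an exponential trend `y = a + b*exp(c*x)`
#'
#' Deterministic initialization: an offset candidate `a0` is placed just
#' outside the data range on each side, `log(|y - a0|)` is regressed on
#' `x` to linearize `b` and `c`, both candidates are polished with
#' bounded Levenberg-Marquardt and the better one is kept.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @return List of class `exp_fit`: `a`, `b`, `c`, `r2`, `converged`.
#' @export
fit_exponential <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 complete pairs")
  margin <- 0.05 * diff(range(y)) + 1e-12
  candidates <- c(min(y) - margin, max(y) + margin)
  best <- NULL
  for (a0 in candidates) {
    z <- y - a0
    s <- sign(z[which.max(abs(z))])
    lz <- log(pmax(abs(z), 1e-12))
    ini <- coef(lm(lz ~ x))
    start <- list(a = a0, b = s * exp(unname(ini[1])), c = unname(ini[2]))
    # one of the two offset candidates is always on the wrong side of the
    # data and may stall at maxiter; that candidate loses the SSE
    # comparison, so its convergence warnings are uninformative
    fit <- tryCatch(
      suppressWarnings(
        nlsLM(y ~ a + b * exp(c * x), data = data.frame(x = x, y = y),
              start = start,
              control = nls.lm.control(maxiter = 500, maxfev = 5000))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          r2 = NA_real_, converged = FALSE),
                     class = "exp_fit"))
  }
  p <- as.list(coef(best$fit))
  structure(list(a = p$a, b = p$b, c = p$c,
                 r2 = .r2(y, fitted(best$fit)), converged = TRUE),
            class = "exp_fit")
}

#' Pairwise correlation matrix with linear and exponential fits
#'
#' For every pair of the given columns, fits an ordinary least squares
#' line and an exponential trend `y = a + b*exp(c*x)`; the model with the
#' higher R2 is marked selected (the exponential only when it converged
#' and beats the line). R2 values are descriptive; no multiplicity
#' control is applied.
#'
#' @param table data frame of numeric columns.
#' @param x_vars,y_vars column names to pair (defaults: all numeric
#'   columns against each other, skipping self-pairs).
#' @return Data frame with one row per (x, y, model) combination:
#'   `x`, `y`, `model`, parameters (`slope`/`intercept` or `a`/`b`/`c`),
#'   `r2`, `selected`, `converged`.
#' @export
correlation_matrix <- function(table, x_vars = NULL, y_vars = NULL) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  if (is.null(x_vars)) x_vars <- num
  if (is.null(y_vars)) y_vars <- num
  rows <- list()
  for (xv in x_vars) for (yv in y_vars) {
    if (xv == yv) next
    x <- table[[xv]]; y <- table[[yv]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4) next
    lin <- lm(y[ok] ~ x[ok])
    lin_r2 <- .r2(y[ok], fitted(lin))
    ex <- tryCatch(fit_exponential(x[ok], y[ok]),
                   error = function(e) structure(
                     list(a = NA, b = NA, c = NA, r2 = NA,
                          converged = FALSE), class = "exp_fit"))
    exp_wins <- isTRUE(ex$converged) && !is.na(ex$r2) && ex$r2 > lin_r2
    rows[[length(rows) + 1L]] <- data.frame(
      x = xv, y = yv, model = "linear",
      slope = unname(coef(lin)[2]), intercept = unname(coef(lin)[1]),
      a = NA_real_, b = NA_real_, c = NA_real_,
      r2 = lin_r2, selected = !exp_wins, converged = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      x = xv, y = yv, model = "exponential",
      slope = NA_real_, intercept = NA_real_,
      a = ex$a, b = ex$b, c = ex$c,
      r2 = ex$r2, selected = exp_wins, converged = ex$converged)
  }
  if (length(rows) == 0) stop("no variable pair with >= 4 complete pairs")
  do.call(rbind, rows)
}

#' Principal component analysis of an attribute table
#'
#' Column-centered and (by default) unit-variance scaled PCA. Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making score plots reproducible across platforms.
#'
#' @param table data frame of numeric columns (>= 2 variables, >= 3
#'   samples).
#' @param scale. scale columns to unit variance (default TRUE).
#' @return List of class `dough_pca`: `scores`, `loadings`,
#'   `explained_pct`, `sdev`.
#' @export
pca_attributes <- function(table, scale. = TRUE) {
  x <- as.matrix(table[vapply(table, is.numeric, TRUE)])
  if (ncol(x) < 2) stop("need >= 2 numeric variables")
  if (nrow(x) < 3) stop("need >= 3 samples")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) stop("zero-variance column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(
    scores = pc$x, loadings = pc$rotation,
    explained_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
    sdev = pc$sdev
  ), class = "dough_pca")
}

#' @export
print.dough_pca <- function(x, ...) {
  cat("<PCA>", length(x$sdev), "components; explained %:",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}
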