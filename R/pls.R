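# NIPALS PLS1 with leave-one-out cross-validation, Root Mean PRESS factor
# selection and VIP scores.

# Core NIPALS PLS1 on a centered/scaled X and centered y. Returns weights
# W (columns unit norm), loadings P, y-loadings q, scores T, and the
# regression vector (on the scaled X) per factor count.
.nipals_pls1 <- function(x0, y0, max_factors) {
  n <- nrow(x0); p <- ncol(x0)
  W <- matrix(0, p, max_factors)
  P <- matrix(0, p, max_factors)
  Tm <- matrix(0, n, max_factors)
  q <- numeric(max_factors)
  ssy <- numeric(max_factors)
  x <- x0; y <- y0
  a <- 0L
  for (k in seq_len(max_factors)) {
    w <- drop(crossprod(x, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, sqrt(sum(y0^2)))) break   # X exhausted
    w <- w / nw
    # with a single response the NIPALS weight update w <- X'y/||X'y|| is
    # already its own fixed point, so no inner iteration is required
    t_ <- drop(x %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-300) break
    p_ <- drop(crossprod(x, t_)) / tt
    q_ <- sum(y * t_) / tt
    x <- x - tcrossprod(t_, p_)
    y <- y - t_ * q_
    a <- k
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- t_; q[k] <- q_
    ssy[k] <- q_^2 * tt
  }
  if (a == 0L) stop("X carries no covariance with y (constant y?)")
  keep <- seq_len(a)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]; ssy <- ssy[keep]
  # regression vector on the scaled X at each factor count
  coef_scaled <- sapply(keep, function(k) {
    Wk <- W[, 1:k, drop = FALSE]
    drop(Wk %*% solve(crossprod(P[, 1:k, drop = FALSE], Wk), q[1:k]))
  })
  coef_scaled <- matrix(coef_scaled, nrow = p)
  list(W = W, P = P, scores = Tm, q = q, ssy = ssy,
       coef_scaled = coef_scaled, n_extracted = a)
}

#' Fit a PLS1 model with NIPALS and leave-one-out validation
#'
#' Fits a single-response partial least squares model by the NIPALS
#' algorithm: predictors are autoscaled (centered, unit variance), the
#' response is centered, and X is deflated after each factor. The number
#' of factors is chosen as the minimum of the leave-one-out Root Mean
#' PRESS (`sqrt(PRESS/n)`; the model is refit on each size n-1 subset and
#' the held-out sample predicted at every candidate factor count; ties
#' within 1e-12 go to the smaller count). Coefficients are
#' back-transformed to the original predictor scale with an explicit
#' intercept.
#'
#' @param x predictor data frame or matrix (no missing values).
#' @param y numeric response (already transformed to its linear scale,
#'   see [transform_responses()]).
#' @param max_factors maximum candidate factor count (capped at the
#'   number of extractable factors).
#' @return Object of class `dough_pls`: `n_factors`, `coefficients`
#'   (original scale), `intercept`, `coefficients_by_factor`, `vip`,
#'   `r2y` (%), `press`, `root_mean_press`, `weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `ssy`, `centering`/`scaling` parameters.
#' @examples
#' d <- generate_linked_dataset(n_per_type = 3, noise_cv = 0, seed = 1)
#' m <- fit_pls1(d[c("pw", "br", "apl", "ly", "epr")], log10(d$j_max))
#' m$r2y
#' @export
fit_pls1 <- function(x, y, max_factors = ncol(x)) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (sd(y) == 0) stop("constant response")
  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, sd)
  if (any(x_sd == 0)) stop("zero-variance predictor column(s): ",
                           paste(colnames(x)[x_sd == 0], collapse = ", "))
  x0 <- scale(x, center = x_mean, scale = x_sd)
  y_mean <- mean(y)
  y0 <- y - y_mean
  max_factors <- min(max_factors, ncol(x), nrow(x) - 1L)

  core <- .nipals_pls1(x0, y0, max_factors)
  a_max <- core$n_extracted

  # leave-one-out PRESS per candidate factor count
  n <- nrow(x)
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    xm <- colMeans(x[-i, , drop = FALSE])
    xs <- apply(x[-i, , drop = FALSE], 2, sd)
    if (any(xs == 0)) stop("zero-variance predictor in a leave-one-out fold")
    ym <- mean(y[-i])
    sub <- .nipals_pls1(scale(x[-i, , drop = FALSE], xm, xs), y[-i] - ym,
                        a_max)
    xi <- (x[i, ] - xm) / xs
    for (k in seq_len(a_max)) {
      kk <- min(k, sub$n_extracted)
      pred <- ym + sum(xi * sub$coef_scaled[, kk])
      press[k] <- press[k] + (y[i] - pred)^2
    }
  }
  rmp <- sqrt(press / n)
  n_factors <- which(rmp <= min(rmp) + 1e-12)[1]

  b_scaled <- core$coef_scaled[, n_factors]
  b <- b_scaled / x_sd
  intercept <- y_mean - sum(b * x_mean)
  yhat <- drop(x %*% b) + intercept
  r2y <- 100 * (1 - sum((y - yhat)^2) / sum((y - y_mean)^2))

  model <- structure(list(
    n_factors = n_factors,
    coefficients = setNames(b, colnames(x)),
    intercept = intercept,
    coefficients_by_factor = sweep(core$coef_scaled, 1, x_sd, `/`),
    weights = core$W, x_loadings = core$P, y_loadings = core$q,
    scores = core$scores, ssy = core$ssy,
    press = press, root_mean_press = rmp,
    r2y = r2y,
    centering = list(x = x_mean, y = y_mean), scaling = x_sd,
    n = n, max_factors = a_max
  ), class = "dough_pls")
  model$vip <- vip_scores(model)
  model
}

#' Variable importance for projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` over the
#' selected factors, where `w_a` are the unit-norm NIPALS weight vectors
#' and `SSY_a` the response variance explained by factor a. The mean
#' squared VIP over predictors is 1 by construction; predictors with
#' VIP > 0.8 are conventionally flagged as important.
#'
#' @param model a fitted [fit_pls1()] model.
#' @param n_factors factor count over which to accumulate (default the
#'   model's selected count).
#' @return Named numeric vector of VIP scores with attribute
#'   `"important"` (logical, VIP > 0.8).
#' @export
vip_scores <- function(model, n_factors = model$n_factors) {
  stopifnot(inherits(model, "dough_pls"))
  k <- seq_len(n_factors)
  W <- model$weights[, k, drop = FALSE]
  ssy <- model$ssy[k]
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- names(model$coefficients)
  attr(vip, "important") <- vip > 0.8
  vip
}

#' @export
print.dough_pls <- function(x, ...) {
  cat(sprintf("<PLS1 model> %d factor(s) (Root Mean PRESS minimum), R2Y = %.2f%%\n",
              x$n_factors, x$r2y))
  cat("coefficients (original predictor scale):\n")
  print(c(x$coefficients, `(intercept)` = x$intercept))
  cat("VIP: ", paste(sprintf("%s %.2f%s", names(x$vip), x$vip,
                             ifelse(attr(x$vip, "important"), "*", "")),
                     collapse = ", "), "   (* > 0.8)\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object a `dough_pls` model.
#' @param newdata data frame or matrix holding the predictor columns.
#' @param n_factors factor count (default the selected one).
#' @param ... unused.
#' @return Numeric vector of predictions on the (transformed) response
#'   scale.
#' @export
predict.dough_pls <- function(object, newdata, n_factors = object$n_factors,
                              ...) {
  b <- object$coefficients_by_factor[, n_factors]
  x <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  intercept <- object$centering$y - sum(b * object$centering$x)
  drop(x %*% b) + intercept
}

#' Fit PLS1 models for every rheological response
#'
#' Transforms the responses to their linear scales and fits one PLS1
#' model per response.
#'
#' @param data data frame holding the five predictors and the response
#'   columns on the natural scale.
#' @param responses response names (default all eight).
#' @param max_factors per-model factor cap.
#' @return Named list of `dough_pls` models.
#' @export
fit_all_pls <- function(data, responses = RHEO_NAMES, max_factors = 5) {
  transformed <- transform_responses(data)
  setNames(lapply(responses, function(r) {
    fit_pls1(data[MICRO_NAMES], transformed[[r]], max_factors = max_factors)
  }), responses)
}
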