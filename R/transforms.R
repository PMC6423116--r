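#' Response linearization transforms
#'
#' The rheological responses are linearized before regression on the
#' microstructural attributes: the creep-recovery compliances and the
#' steady-state viscosity vary over decades and enter on a log10 scale,
#' the oscillatory stiffness quantities enter reciprocally, and the
#' dimensionless responses are left untouched.
#'
#' @return Named character vector mapping each of the eight responses to
#'   `"log10"`, `"reciprocal"` or `"identity"`.
#' @export
response_transforms <- function() {
  c(j_max = "log10", j_r = "log10", eta0 = "log10",
    g_star = "reciprocal", a_f = "reciprocal",
    j_el = "identity", tan_delta = "identity", z = "identity")
}

.apply_transform <- function(x, transform, what = "value") {
  switch(transform,
    identity = x,
    log10 = {
      if (any(x <= 0)) stop("nonpositive ", what, " cannot be log10-transformed")
      log10(x)
    },
    reciprocal = {
      if (any(x <= 0)) stop("nonpositive ", what, " cannot be reciprocal-transformed")
      1 / x
    },
    stop("unknown transform: ", transform)
  )
}

#' Inverse of a response transform
#'
#' @param x transformed values.
#' @param transform `"identity"`, `"log10"` or `"reciprocal"`.
#' @return Natural-scale values (`10^x` for log10, `1/x` for reciprocal).
#'   Reciprocal back-transforms of nonpositive values yield nonpositive
#'   results; callers flag these as non-physical rather than erroring.
#' @export
inverse_transform_values <- function(x, transform) {
  switch(transform,
    identity = x,
    log10 = 10^x,
    reciprocal = 1 / x,
    stop("unknown transform: ", transform)
  )
}

#' Transform a response table to the linearized scale
#'
#' @param table data frame holding (some of) the eight rheological
#'   response columns on the natural scale.
#' @param transforms named transform map, default [response_transforms()].
#' @return The table with every mapped column transformed in place; the
#'   transform map is attached as attribute `"transforms"`.
#' @examples
#' transform_responses(data.frame(j_max = 0.01, g_star = 20000))
#' @export
transform_responses <- function(table, transforms = response_transforms()) {
  for (nm in intersect(names(transforms), names(table))) {
    table[[nm]] <- .apply_transform(table[[nm]], transforms[[nm]],
                                    what = paste0(nm, " value"))
  }
  attr(table, "transforms") <- transforms
  table
}

#' Back-transform a linearized response table
#'
#' Inverse of [transform_responses()].
#'
#' @inheritParams transform_responses
#' @return Natural-scale table.
#' @export
inverse_transform_responses <- function(table,
                                        transforms = response_transforms()) {
  for (nm in intersect(names(transforms), names(table))) {
    table[[nm]] <- inverse_transform_values(table[[nm]], transforms[[nm]])
  }
  table
}
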