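# Three-step classification into the six gluten network types:
# lacunarity range -> candidate set; attribute directions vs. standard;
# best-agreement assignment.

#' Lacunarity bin and candidate network types
#'
#' Bins a lacunarity value into the classification ranges. Bins are
#' half-open at the top (0.16, 0.26 and 0.5 belong to the lower bin).
#'
#' @param ly lacunarity (>= 0).
#' @return List with `bin` (printable range), `candidates` (network type
#'   names sharing the bin).
#' @examples
#' lacunarity_bin(0.22)$candidates
#' @export
lacunarity_bin <- function(ly) {
  if (!is.finite(ly) || ly < 0) stop("lacunarity must be >= 0")
  if (ly <= 0.16) {
    list(bin = "[0, 0.16]", candidates = "cleaved")
  } else if (ly <= 0.26) {
    list(bin = "(0.16, 0.26]",
         candidates = c("rigid", "spread", "strengthened"))
  } else if (ly <= 0.5) {
    list(bin = "(0.26, 0.5]", candidates = "particulate_dense")
  } else {
    list(bin = "(0.5, Inf)", candidates = "particulate_loose")
  }
}

#' Attribute direction vector relative to a standard dough
#'
#' Per attribute: `+1` if the sample exceeds `(1 + tol)` times the
#' standard, `-1` if it falls below `(1 - tol)` times the standard, `0`
#' otherwise.
#'
#' @param sample,standard [micro_attributes()] vectors (standard > 0).
#' @param tol relative dead-band (default 0.10; configuration, the
#'   classification scheme itself gives only ordinal arrows).
#' @return Named integer vector of signs over `pw`, `br`, `apl`, `ly`,
#'   `epr`.
#' @export
direction_vector <- function(sample, standard, tol = 0.10) {
  sample <- as_micro_attributes(sample)
  standard <- as_micro_attributes(standard)
  if (any(standard <= 0)) stop("standard attributes must be > 0")
  ratio <- unclass(sample) / unclass(standard)
  sign <- integer(length(ratio))
  sign[ratio > 1 + tol] <- 1L
  sign[ratio < 1 - tol] <- -1L
  setNames(sign, names(ratio))
}

# Agreement score of a sample sign vector against an archetype's arrow
# pattern: +1 per matching sign, -1 per contradiction, 0 when either side
# is neutral. `weight_double` doubles the stake on double-arrow
# attributes.
.match_score <- function(signs, arrows, weight_double = FALSE) {
  pat <- .arrow_sign(arrows)
  w <- if (weight_double) ifelse(arrows %in% c("--", "++"), 2, 1)
       else rep(1, length(arrows))
  s <- signs[names(arrows)]
  sum(w * ifelse(pat == 0L | s == 0L,
                 ifelse(pat == s, 1, 0),      # both neutral -> match
                 ifelse(pat == s, 1, -1)))
}

#' Classify a sample into a gluten network type
#'
#' Three-step scheme: (1) the lacunarity range selects the candidate
#' types; (2) the five attributes are compared with the corresponding
#' standard dough and collapsed to signs ([direction_vector()]); (3) each
#' candidate's arrow pattern is scored (+1 match / 0 neutral / -1
#' contradiction per attribute) and the best-scoring candidate is
#' assigned. Ties set the `ambiguous` flag and list all top candidates.
#'
#' @inheritParams direction_vector
#' @param weight_double score double arrows (strong increases/decreases)
#'   with weight 2 (default FALSE).
#' @return List of class `classification_result`: `assigned` (network
#'   type name), `archetype` ([archetype_spec()]), `lacunarity_bin`,
#'   `candidates`, `direction_vector`, `match_scores`, `ambiguous`,
#'   `top_candidates`.
#' @examples
#' std <- standard_dough_attributes()
#' weak <- micro_attributes(pw = 3, br = 0.005, apl = 22, ly = 0.10,
#'                          epr = 0.011)
#' classify_network(weak, std)$assigned   # "cleaved"
#' @export
classify_network <- function(sample, standard, tol = 0.10,
                             weight_double = FALSE) {
  sample <- as_micro_attributes(sample)
  bin <- lacunarity_bin(sample[["ly"]])
  signs <- direction_vector(sample, standard, tol)
  scores <- vapply(bin$candidates, function(type) {
    .match_score(signs, ARCHETYPE_DIRECTIONS[[type]], weight_double)
  }, numeric(1))
  top <- names(scores)[scores == max(scores)]
  assigned <- top[1]
  ambiguous <- length(top) > 1
  if (ambiguous) {
    # standard-like samples in the mid-lacunarity bin default to spread
    if ("spread" %in% top) assigned <- "spread"
  }
  structure(list(
    assigned = assigned,
    archetype = archetype_spec(assigned),
    lacunarity_bin = bin$bin,
    candidates = bin$candidates,
    direction_vector = signs,
    match_scores = scores,
    ambiguous = ambiguous,
    top_candidates = top
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("assigned: %s%s  [lacunarity bin %s]\n", x$assigned,
              if (x$ambiguous)
                paste0(" (ambiguous: ", paste(x$top_candidates,
                                              collapse = "/"), ")")
              else "", x$lacunarity_bin))
  cat("directions:",
      paste(names(x$direction_vector),
            c("-", "0", "+")[x$direction_vector + 2L], collapse = ", "),
      "\n")
  cat("scores:", paste(names(x$match_scores), x$match_scores,
                       sep = " ", collapse = ", "), "\n")
  invisible(x)
}

#' Check a classification against the sample's viscosity level
#'
#' Each network type carries a qualitative rheological character (low
#' viscous / viscoelastic / highly viscous). This check places the
#' sample's steady-state viscosity `eta0` into terciles of a cohort and
#' reports whether the tercile matches the assigned type's character. A
#' mismatch is reported only; the microstructural assignment is never
#' overridden.
#'
#' @param result a [classify_network()] result.
#' @param rheo the sample's [rheo_attributes()] (only `eta0` is used).
#' @param cohort data frame or vector of cohort `eta0` values (>= 3).
#' @return List: `consistent` (`TRUE`/`FALSE`/`NA` for indeterminate),
#'   `expected_level`, `observed_tercile`, `note`.
#' @export
rheology_consistency <- function(result, rheo, cohort) {
  stopifnot(inherits(result, "classification_result"))
  eta0 <- if (is.numeric(rheo) && !is.null(names(rheo))) rheo[["eta0"]]
          else rheo$eta0
  cohort_eta0 <- if (is.data.frame(cohort)) cohort$eta0 else cohort
  if (length(cohort_eta0) < 3) stop("cohort must hold >= 3 samples")
  qs <- quantile(cohort_eta0, c(1 / 3, 2 / 3), names = FALSE)
  if (qs[1] == qs[2]) {
    return(list(consistent = NA, expected_level = NA_character_,
                observed_tercile = NA_character_,
                note = "indeterminate: degenerate cohort terciles"))
  }
  tercile <- if (eta0 <= qs[1]) "low" else if (eta0 <= qs[2]) "middle"
             else "top"
  expected <- ARCHETYPE_RHEOLOGY[[result$assigned]]
  expected_tercile <- switch(expected, low_viscous = "low",
                             viscoelastic = "middle",
                             highly_viscous = "top")
  consistent <- tercile == expected_tercile
  list(consistent = consistent, expected_level = expected,
       observed_tercile = tercile,
       note = if (consistent) "viscosity level matches network type"
              else sprintf("assigned type expects %s viscosity but eta0 sits in the %s tercile",
                           gsub("_", " ", expected), tercile))
}

#' Classify every row of an attribute table
#'
#' @param table data frame with the five attribute columns.
#' @param standard standard-dough attributes.
#' @param tol direction dead-band.
#' @return The table with added columns `assigned`, `lacunarity_bin`,
#'   `ambiguous` and per-candidate score columns `score_<type>` (NA when
#'   a type is not a candidate).
#' @export
classify_table <- function(table, standard = standard_dough_attributes(),
                           tol = 0.10) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    classify_network(as_micro_attributes(table[i, ]), standard, tol)
  })
  table$assigned <- vapply(res, `[[`, "", "assigned")
  table$lacunarity_bin <- vapply(res, `[[`, "", "lacunarity_bin")
  table$ambiguous <- vapply(res, `[[`, TRUE, "ambiguous")
  for (type in NETWORK_TYPES) {
    table[[paste0("score_", type)]] <- vapply(res, function(r) {
      if (type %in% names(r$match_scores)) r$match_scores[[type]]
      else NA_real_
    }, numeric(1))
  }
  table
}
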