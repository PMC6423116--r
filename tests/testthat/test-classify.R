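test_that("lacunarity bins follow the published ranges", {
  expect_equal(lacunarity_bin(0.10)$candidates, "cleaved")
  expect_setequal(lacunarity_bin(0.22)$candidates,
                  c("rigid", "spread", "strengthened"))
  expect_equal(lacunarity_bin(0.35)$candidates, "particulate_dense")
  expect_equal(lacunarity_bin(0.60)$candidates, "particulate_loose")
  # half-open boundaries: the edge belongs to the lower bin
  expect_equal(lacunarity_bin(0.16)$candidates, "cleaved")
  expect_equal(lacunarity_bin(0.26)$candidates[1], "rigid")
  expect_equal(lacunarity_bin(0.5)$candidates, "particulate_dense")
  expect_error(lacunarity_bin(-0.1), ">= 0")

  # the candidate set changes exactly at the three boundaries
  lys <- seq(0, 0.7, by = 0.001)
  sets <- vapply(lys, function(l)
    paste(lacunarity_bin(l)$candidates, collapse = "+"), "")
  changes <- lys[which(sets[-1] != sets[-length(sets)]) + 1]
  expect_equal(changes, c(0.161, 0.261, 0.501), tolerance = 1e-9)
})

test_that("direction vectors compare against the standard with a dead band", {
  std <- standard_dough_attributes()
  expect_equal(unname(direction_vector(std, std)), rep(0L, 5))
  dbl <- micro_attributes(std[["pw"]], std[["br"]], std[["apl"]],
                          2 * std[["ly"]], std[["epr"]])
  expect_equal(direction_vector(dbl, std)[["ly"]], 1L)

  # tol = 0: signs equal an exhaustive elementwise comparison
  set.seed(44)
  for (k in 1:20) {
    sample <- micro_attributes(pw = std[["pw"]] * runif(1, 0.99, 1.01),
                               br = std[["br"]] * runif(1, 0.99, 1.01),
                               apl = std[["apl"]] * runif(1, 0.99, 1.01),
                               ly = std[["ly"]] * runif(1, 0.99, 1.01),
                               epr = std[["epr"]] * runif(1, 0.99, 1.01))
    got <- direction_vector(sample, std, tol = 0)
    want <- sign(unclass(sample) - unclass(std))
    expect_equal(unname(got), unname(want))
  }
  expect_error(direction_vector(std, micro_attributes(0, 1, 1, 1, 1)),
               "> 0")
})

test_that("textbook samples classify to their published types", {
  std <- standard_dough_attributes()
  # weak dough: endpoints way up, branching down, low lacunarity
  weak <- micro_attributes(pw = 1.3 * std[["pw"]], br = 0.5 * std[["br"]],
                           apl = 0.8 * std[["apl"]], ly = 0.10,
                           epr = 2 * std[["epr"]])
  r1 <- classify_network(weak, std)
  expect_equal(r1$assigned, "cleaved")
  expect_match(r1$archetype$description, "Ruptured")

  # dense continuous network: branching and length up, endpoints down
  rigid <- micro_attributes(pw = 0.8 * std[["pw"]], br = 2 * std[["br"]],
                            apl = 2 * std[["apl"]], ly = 0.18,
                            epr = 0.5 * std[["epr"]])
  r2 <- classify_network(rigid, std)
  expect_equal(r2$assigned, "rigid")
  expect_false(r2$ambiguous)

  # very high lacunarity: the bin alone decides
  loose <- micro_attributes(pw = std[["pw"]], br = std[["br"]],
                            apl = std[["apl"]], ly = 0.60,
                            epr = std[["epr"]])
  r3 <- classify_network(loose, std)
  expect_equal(r3$assigned, "particulate_loose")
  expect_equal(r3$candidates, "particulate_loose")
})

test_that("each archetype pattern is a fixed point of the classifier", {
  std <- standard_dough_attributes()
  for (ty in names(network_archetypes())) {
    sample <- generate_attribute_table(ty, std, n = 1, noise_cv = 0)
    res <- classify_network(as_micro_attributes(sample[1, ]), std)
    expect_equal(res$assigned, ty)
    expect_gte(res$match_scores[[ty]], max(res$match_scores))
  }
})

test_that("every input yields exactly one assignment or a flagged tie", {
  std <- standard_dough_attributes()
  set.seed(77)
  for (k in 1:200) {
    sample <- micro_attributes(pw = runif(1, 0.1, 10),
                               br = runif(1, 1e-4, 0.1),
                               apl = runif(1, 1, 100),
                               ly = runif(1, 0, 1.2),
                               epr = runif(1, 1e-4, 0.1))
    res <- classify_network(sample, std)
    expect_true(res$assigned %in% res$candidates)
    expect_length(res$assigned, 1)
    expect_gte(res$match_scores[[res$assigned]], max(res$match_scores))
    if (res$ambiguous) expect_gt(length(res$top_candidates), 1)
  }
})

test_that("generated attribute tables classify back to their labels", {
  std <- standard_dough_attributes()
  acc <- vapply(1:20, function(s) {
    hits <- 0L; n <- 0L
    for (ty in names(network_archetypes())) {
      tab <- generate_attribute_table(ty, std, n = 5, noise_cv = 0.1,
                                      seed = s * 100 + nchar(ty))
      got <- classify_table(tab, std)$assigned
      hits <- hits + sum(got == ty); n <- n + length(got)
    }
    hits / n
  }, numeric(1))
  expect_gte(median(acc), 0.9)
})

test_that("viscosity terciles cross-check the assigned type", {
  std <- standard_dough_attributes()
  dense <- classify_network(
    micro_attributes(3, 0.005, 15, 0.38, 0.01), std)
  expect_equal(dense$assigned, "particulate_dense")
  cohort <- c(1e4, 5e4, 1e5, 5e5, 1e6, 5e6)
  high <- list(eta0 = 4e6)
  low <- list(eta0 = 2e4)
  expect_true(rheology_consistency(dense, high, cohort)$consistent)
  # a highly viscous reading contradicts a low-viscous (cleaved) type
  cleaved <- classify_network(
    micro_attributes(3.2, 0.005, 24, 0.10, 0.01), std)
  expect_equal(cleaved$assigned, "cleaved")
  expect_false(rheology_consistency(cleaved, high, cohort)$consistent)
  expect_true(rheology_consistency(cleaved, low, cohort)$consistent)
  # degenerate cohort: indeterminate
  flat <- rheology_consistency(dense, high, rep(1e5, 5))
  expect_true(is.na(flat$consistent))
  expect_match(flat$note, "indeterminate")
  expect_error(rheology_consistency(dense, high, c(1, 2)), ">= 3")
})
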