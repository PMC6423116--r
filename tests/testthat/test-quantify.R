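test_that("binarization thresholds correctly and flags degenerate input", {
  expect_error(binarize(matrix(0.5, 8, 8)), "constant image")
  # bimodal image: Otsu separates the brighter mode
  m <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
  img <- binarize(m)
  expect_equal(sum(img$pixels), 32)
  expect_true(all(img$pixels[m > 0.5] == 1L))
  # ramp with a fixed threshold: foreground fraction is the analytic count
  ramp <- matrix(seq(0, 1, length.out = 100), 10, 10)
  img2 <- binarize(ramp, method = "fixed", threshold = 0.7)
  expect_equal(sum(img2$pixels), sum(ramp > 0.7))
  # fully binary input passes through
  expect_equal(binarize(matrix(c(0, 1), 4, 4))$pixels[1, 1], 0L)
  expect_error(binarize(matrix(c(0.2, 0.4), 4, 4), method = "fixed",
                        threshold = 0.9), "all-background")
})

test_that("skeleton tracing recovers canonical shapes", {
  # open bar: one component, two endpoints, no junctions
  g <- skeletonize_and_trace(calibrated_image(bar_image(), 1))
  expect_length(g$component_lengths_um, 1)
  expect_equal(g$n_endpoints, 2)
  expect_equal(g$n_junctions, 0)
  # cross: one junction, four endpoints
  g2 <- skeletonize_and_trace(calibrated_image(cross_image(), 1))
  expect_equal(g2$n_junctions, 1)
  expect_equal(g2$n_endpoints, 4)
  # annulus: a single closed curve
  g3 <- skeletonize_and_trace(calibrated_image(annulus_image(), 1))
  expect_length(g3$component_lengths_um, 1)
  expect_equal(g3$n_endpoints, 0)
  expect_equal(g3$n_junctions, 0)
  # component lengths sum to the total length
  expect_equal(sum(g2$component_lengths_um), g2$total_length_um)
  expect_error(skeletonize_and_trace(calibrated_image(matrix(0L, 8, 8))),
               "empty foreground")
})

test_that("a single straight segment yields the textbook attributes", {
  # 100 um one-pixel-wide segment at 1 um/px
  m <- matrix(0L, 120, 120)
  m[60, 10:110] <- 1L
  at <- quantify_micrograph(calibrated_image(m, 1), box_sizes = c(8, 16))
  expect_equal(at[["apl"]], 100, tolerance = 1 / 100)   # +-1 px
  expect_equal(at[["br"]], 0)
  expect_equal(at[["epr"]], 2 / 101, tolerance = 1e-10)
  expect_equal(at[["pw"]], 101 / 100, tolerance = 1e-10)
})

test_that("gliding-box lacunarity matches the exhaustive oracle", {
  set.seed(42)
  m <- matrix(rbinom(256 * 256, 1, 0.3), 256, 256)
  got <- attr(gliding_box_lacunarity(m, box_sizes = 16), "by_box")[["16"]]
  expect_equal(got, brute_force_lacunarity(m, 16), tolerance = 1e-12)
  # a filled image has zero lacunarity at every box size
  expect_equal(as.numeric(gliding_box_lacunarity(matrix(1L, 64, 64),
                                                 c(8, 16, 32))), 0)
  # strided large-box scan stays close to the exhaustive one
  big <- gliding_box_lacunarity(m, box_sizes = 64)
  big_ex <- gliding_box_lacunarity(m, box_sizes = 64, exhaustive = TRUE)
  expect_equal(as.numeric(big), as.numeric(big_ex), tolerance = 0.05)
  expect_error(gliding_box_lacunarity(matrix(1L, 16, 16), box_sizes = 32),
               "no box size")
})

test_that("attributes transform correctly under calibration and rotation", {
  set.seed(11)
  img <- generate_network_image("spread", size_px = 256, seed = 11)
  at1 <- quantify_micrograph(calibrated_image(img$pixels, 0.21),
                             box_sizes = c(8, 16, 32))
  at2 <- quantify_micrograph(calibrated_image(img$pixels, 0.42),
                             box_sizes = c(8, 16, 32))
  expect_equal(at2[["apl"]], 2 * at1[["apl"]], tolerance = 1e-12)
  expect_equal(at2[["pw"]], 2 * at1[["pw"]], tolerance = 1e-12)
  expect_equal(at2[["br"]], at1[["br"]] / 4, tolerance = 1e-12)
  expect_equal(at2[["epr"]], at1[["epr"]] / 4, tolerance = 1e-12)
  expect_equal(at2[["ly"]], at1[["ly"]], tolerance = 1e-12)

  # 90 degree rotation: raster-level quantities are exactly invariant;
  # skeleton-derived ones shift marginally (thinning subiterations carry
  # a directional bias) and are held to tight relative bounds instead
  rot <- t(img$pixels)[ncol(img$pixels):1, ]
  at3 <- quantify_micrograph(calibrated_image(rot, 0.21),
                             box_sizes = c(8, 16, 32))
  expect_equal(at3[["ly"]], at1[["ly"]], tolerance = 1e-12)
  d1 <- attr(at1, "details"); d3 <- attr(at3, "details")
  expect_equal(d3$protein_area_um2, d1$protein_area_um2, tolerance = 1e-12)
  expect_equal(at3[["pw"]], at1[["pw"]], tolerance = 0.02)
  expect_equal(at3[["apl"]], at1[["apl"]], tolerance = 0.02)
  expect_equal(at3[["br"]], at1[["br"]], tolerance = 0.06)
  expect_equal(at3[["epr"]], at1[["epr"]], tolerance = 0.06)
})

test_that("lacunarity ranks heterogeneity as the theory demands", {
  # nested fixtures: progressively more homogeneous -> smaller ly
  set.seed(5)
  sparse_clustered <- matrix(0L, 128, 128)
  for (k in 1:4) {
    ci <- sample(20:108, 1); cj <- sample(20:108, 1)
    sparse_clustered[(ci - 8):(ci + 8), (cj - 8):(cj + 8)] <- 1L
  }
  uniform <- matrix(0L, 128, 128)
  uniform[, seq(2, 128, by = 4)] <- 1L   # evenly spread stripes
  boxes <- c(8, 16, 32)
  ly_clustered <- as.numeric(gliding_box_lacunarity(sparse_clustered, boxes))
  ly_uniform <- as.numeric(gliding_box_lacunarity(uniform, boxes))
  expect_gt(ly_clustered, ly_uniform)
  expect_gte(ly_uniform, 0)

  # paired fixtures at equal area fraction: scattered blobs vs a mesh
  set.seed(6)
  blobs <- doughnet:::.draw_blobs(256, n_blobs = 24, radius = 12)
  mesh <- doughnet:::.draw_mesh(256, spacing = 40, width = 3, amp = 3,
                                period = 110)
  frac_b <- mean(blobs); frac_m <- mean(mesh)
  expect_lt(abs(frac_b - frac_m), 0.12)   # comparable coverage
  expect_gt(as.numeric(gliding_box_lacunarity(blobs)),
            as.numeric(gliding_box_lacunarity(mesh)))
})
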