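test_that("circular derivative applies wraparound central differences", {
  p <- intensity_profile(c(1, 2, 3, 2))
  expect_equal(circular_derivative(p), c(0, 1, 0, -1))
  expect_equal(circular_derivative(intensity_profile(rep(4, 6))), rep(0, 6))
  # telescoping: the derivative of any closed profile sums to zero
  set.seed(3)
  for (i in 1:20) {
    v <- stats::rnorm(sample(4:64, 1))
    expect_equal(sum(circular_derivative(intensity_profile(v))), 0,
                 tolerance = 1e-12)
  }
  expect_error(circular_derivative(
    linescan_profile(list(matrix(1:9, 3, 3)), c(1, 1), c(3, 3), 5)[[1]]),
    class = "contract_error")
})

test_that("normalization modes handle ranges and degenerate input", {
  expect_equal(normalize_signal(c(2, 4, 6), "min_max"), c(0, 0.5, 1))
  expect_equal(normalize_signal(c(5, 5, 5), "min_max"), c(0, 0, 0))
  expect_equal(normalize_signal(c(-2, 1), "max_abs"), c(-1, 0.5))
  expect_equal(normalize_signal(c(3, 3), "max_abs"), c(0, 0))
})

test_that("contour sampling interpolates and can preserve integer counts", {
  img <- matrix(1:16, 4, 4) * 10
  ct <- nucleus_contour(rbind(c(2, 2), c(2, 3), c(3, 3), c(3, 2)))
  prof <- sample_contour_intensity(img, ct, quantize = FALSE)
  expect_equal(prof$values, img[as.matrix(unclass(ct))])  # identity at grid points
  # midpoint interpolation (winding normalization may reorder points)
  ct2 <- nucleus_contour(rbind(c(1.5, 1), c(1.5, 4), c(4, 4), c(4, 1)))
  p2 <- sample_contour_intensity(img, ct2, quantize = FALSE)
  at <- which(p2$positions[, 1] == 1.5 & p2$positions[, 2] == 1)
  expect_equal(p2$values[at], mean(img[1:2, 1]))
  out <- nucleus_contour(rbind(c(0.2, 1), c(1, 4), c(4, 4), c(4, 1)))
  expect_error(sample_contour_intensity(img, out), class = "geometry_error")
  expect_equal(sample_contour_intensity(matrix(7.4, 5, 5),
                                        ct, quantize = TRUE)$values, rep(7, 4))
})

test_that("identical profiles give a fluctuation index of exactly zero", {
  set.seed(11)
  cases <- list(
    rep(5, 16),                             # constant
    round(100 + 30 * sin(seq_len(32) / 3)), # smooth with flat stretches
    c(1, 2, 3, 2, 1, 2, 3, 2),              # mixed zero/nonzero derivatives
    stats::rnorm(64))                       # irregular
  for (v in cases) {
    fr <- fluctuation_index(intensity_profile(v), intensity_profile(v))
    expect_identical(fr$index, 0)
  }
})

test_that("the index matches the literal three-step oracle", {
  # sinusoid + one narrow spike, the hand-checkable 16-point fixture
  base <- 100 + 50 * sin(2 * pi * (0:15) / 16)
  spiked <- base; spiked[5] <- spiked[5] + 400
  got <- fluctuation_index(intensity_profile(base), intensity_profile(spiked))
  want <- oracle_fluctuation_index(base, spiked)
  expect_equal(got$index, want$index, tolerance = 1e-12)
  expect_equal(got$fraction_12, want$fraction_12, tolerance = 1e-12)
  # random seeded profile pairs across lengths
  set.seed(19)
  for (i in 1:30) {
    n <- sample(16:256, 1)
    pair <- random_profile_pair(n, list(k = sample(1:5, 1), sd = runif(1, 0, 20),
                                        gain = runif(1, 0.5, 2),
                                        n_spikes = sample(0:6, 1),
                                        spike = runif(1, 50, 500)))
    got <- fluctuation_index(intensity_profile(pair$ref),
                             intensity_profile(pair$test))
    want <- oracle_fluctuation_index(pair$ref, pair$test)
    expect_equal(got$index, want$index, tolerance = 1e-9)
  }
})

test_that("index is swap-symmetric, gain-invariant and bounded", {
  set.seed(23)
  for (i in 1:10) {
    pair <- random_profile_pair(48, list(k = 3, sd = 8, gain = 1.3,
                                         n_spikes = 3, spike = 200))
    ref <- intensity_profile(pair$ref); tst <- intensity_profile(pair$test)
    fr <- fluctuation_index(ref, tst)
    sw <- fluctuation_index(tst, ref)
    expect_equal(sw$fraction_12, fr$fraction_21)
    expect_equal(sw$fraction_21, fr$fraction_12)
    expect_equal(sw$index, fr$index)
    # power-of-two gain: exact in floating point, so invariance is bitwise
    gained <- fluctuation_index(ref, intensity_profile(tst$values * 8))
    expect_equal(gained$index, fr$index)
    expect_gte(fr$index, 0); expect_lte(fr$index, 200)
    expect_true(all(fr$ratio_12 >= 0 & fr$ratio_12 <= 1))
    expect_true(all(fr$ratio_21 >= 0 & fr$ratio_21 <= 1))
  }
  expect_error(fluctuation_index(intensity_profile(1:6), intensity_profile(1:6)),
               class = "contract_error")  # fewer than 8 positions
  expect_error(fluctuation_index(intensity_profile(1:8), intensity_profile(1:9)),
               class = "contract_error")
})

test_that("punctate profiles find their foci and outscore uniform ones", {
  sp <- fixture_punctate_spec()
  img <- generate_nucleus_image(sp)
  # sample both noiseless channels on the true contour; their ratio cancels
  # the shared envelope brightness, leaving the focal pattern, whose peaks
  # must align with the ground-truth focus angles
  tprof <- sample_contour_intensity(
    max_intensity_projection(img$stack, "test"), img$truth$contour,
    quantize = FALSE)
  rprof <- sample_contour_intensity(
    max_intensity_projection(img$stack, "reference"), img$truth$contour,
    quantize = FALSE)
  focal <- tprof$values / pmax(rprof$values, 1)
  angles <- img$truth$boundary_angles
  for (fa in img$truth$focus_angles) {
    near <- abs(atan2(sin(angles - fa), cos(angles - fa))) < sp$focus_arc_sigma
    expect_gt(max(focal[near]), 3 * stats::median(focal))
  }
  # pipeline indices: punctate clearly above the uniform fixture
  pp <- pipeline_profiles(img)
  up <- pipeline_profiles(generate_nucleus_image(fixture_uniform_spec()))
  expect_gt(fluctuation_index(pp$ref, pp$test)$index,
            fluctuation_index(up$ref, up$test)$index)
})

test_that("linescan profiles scale each channel to a maximum of 100", {
  img <- matrix(0, 8, 8); img[5, ] <- c(2, 4, 8, 6, 2, 1, 1, 1)
  prof <- linescan_profile(list(img), c(5, 1), c(5, 8), n_samples = 8)[[1]]
  expect_equal(prof$values, c(25, 50, 100, 75, 25, 12.5, 12.5, 12.5))
  expect_false(prof$circular)
  expect_equal(linescan_profile(list(matrix(3, 4, 4)), c(1, 1), c(4, 4),
                                5)[[1]]$values, rep(100, 5))
  expect_error(linescan_profile(list(img), c(2, 2), c(2, 2)),
               class = "geometry_error")
  # peak of a punctate linescan sits on the focus crossing
  sp <- synthetic_spec(n_foci = 1L, focus_contrast = 10,
                       baseline_fraction = 0.05, focus_placement = "spaced",
                       noise = "none")
  img2 <- generate_nucleus_image(sp)
  fa <- img2$truth$focus_angles[1]
  i <- which.min(abs(img2$truth$boundary_angles - fa))
  pt <- img2$truth$contour[i, ]
  dirv <- pt - sp$center
  dirv <- dirv / sqrt(sum(dirv^2))
  p0 <- pt - 6 * dirv; p1 <- pt + 6 * dirv
  ls <- linescan_profile(list(rimfluct:::as_matrix(
    max_intensity_projection(img2$stack, "test"))), p0, p1, n_samples = 25)[[1]]
  expect_lt(abs(which.max(ls$values) - 13), 1.5)
})
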