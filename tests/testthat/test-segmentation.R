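test_that("Otsu threshold maximizes between-class variance", {
  # forced two-class example
  img <- matrix(c(1, 1, 1, 1, 9, 9), 2, 3)
  res <- otsu_threshold(img)
  expect_gt(res$threshold, 1)
  expect_lt(res$threshold, 9)
  expect_equal(sum(res$mask), 2)
  # exhaustive oracle on random 8-bit histograms
  set.seed(7)
  for (i in 1:50) {
    x <- matrix(sample.int(256, 400, replace = TRUE,
                           prob = runif(256)^2) - 1, 20, 20)
    if (max(x) == min(x)) next
    res <- otsu_threshold(x)
    achieved <- oracle_otsu_variance(as.numeric(x), res$threshold)
    best <- oracle_otsu_best_variance(as.numeric(x))
    expect_equal(achieved, best, tolerance = 1e-10)
  }
  expect_error(otsu_threshold(matrix(5, 3, 3)), class = "degenerate_error")
})

test_that("Otsu mask recovers the counterstain ellipse area", {
  sp <- fixture_uniform_spec()
  img <- generate_nucleus_image(sp)
  res <- otsu_threshold(max_intensity_projection(img$stack, "counterstain"))
  true_area <- pi * sp$semi_axes[1] * sp$semi_axes[2]
  expect_lt(abs(sum(res$mask) - true_area) / true_area, 0.05)
})

test_that("initial boundaries trace retained components in order", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  cts <- initial_boundary(m, min_area = 4, n_points = 16)
  expect_length(cts, 1)
  expect_equal(nrow(cts[[1]]), 16)
  # all points on the border of the 3x3 square (within half a pixel)
  expect_true(all(cts[[1]] >= 1.5 & cts[[1]] <= 4.5))
  # second blob below min_area is dropped
  m2 <- m; m2[1, 5] <- TRUE
  expect_length(initial_boundary(m2, min_area = 4), 1)
  expect_error(initial_boundary(m2 & FALSE, min_area = 1),
               class = "degenerate_error")
  # synthetic ellipse mask: mean radial distance to the true ellipse <= 1 px
  sp <- fixture_uniform_spec()
  img <- generate_nucleus_image(sp)
  res <- otsu_threshold(max_intensity_projection(img$stack, "counterstain"))
  ct <- initial_boundary(res$mask, min_area = 200)[[1]]
  d <- vapply(seq_len(nrow(ct)), function(i)
    oracle_point_ellipse_distance(ct[i, ], sp$center, sp$semi_axes,
                                  sp$orientation), 1)
  expect_lt(mean(d), 1)
})

test_that("contours are closed, consistently wound and resampled", {
  sq <- rbind(c(1, 1), c(1, 5), c(5, 5), c(5, 1))  # clockwise in (y,x)
  ct <- nucleus_contour(sq)
  expect_gt(rimfluct:::signed_area(ct), 0)   # winding normalized
  rs <- rimfluct:::resample_closed(ct, 40)
  expect_equal(nrow(rs), 40)
  seg <- sqrt(rowSums((rs - rs[c(2:40, 1), ])^2))
  expect_lt(max(seg) - min(seg), 1e-6)       # uniform arc-length spacing
})

test_that("edge maps ridge on intensity steps and rims", {
  expect_equal(max(edge_map(matrix(3, 8, 8), sigma = 1)), 0)
  step <- matrix(0, 16, 16); step[, 9:16] <- 10
  em <- edge_map(step, sigma = 1)
  expect_true(all(apply(em[4:13, ], 1, which.max) %in% 8:9))
  expect_equal(max(em), 1)
  # rim image: edge ridge of the counterstain lies on the boundary
  sp <- fixture_uniform_spec()
  img <- generate_nucleus_image(sp)
  em2 <- edge_map(max_intensity_projection(img$stack, "counterstain"), sigma = 1.5)
  ct <- img$truth$contour
  ridge_val <- rimfluct:::bilinear_sample(rimfluct:::as_matrix(em2),
                                          ct[, 1], ct[, 2])
  expect_gt(mean(ridge_val), 0.5 * max(em2))
})

test_that("GVF field behaves at its fixed points and limits", {
  z <- matrix(0, 10, 10)
  f0 <- compute_gvf(z, n_iterations = 25)
  expect_equal(max(abs(f0$vy)), 0)
  expect_equal(max(abs(f0$vx)), 0)
  step <- matrix(0, 12, 12); step[, 7:12] <- 1
  raw <- compute_gvf(step, n_iterations = 0)
  gr <- rimfluct:::gradient2d(step)
  expect_equal(raw$vx, gr$gx)
  expect_equal(raw$vy, gr$gy)
  # edge map of a step is a ridge at the step; after diffusion the field on
  # both sides points toward that ridge
  em <- edge_map(step, sigma = 1)
  ridge_col <- which.max(colSums(em))
  f <- compute_gvf(em, mu = 0.2, dt = 1, n_iterations = 60)
  expect_true(all(f$vx[, 2:(ridge_col - 2)] > 0))       # push right
  expect_true(all(f$vx[, (ridge_col + 2):11] < 0))      # push left
  expect_error(compute_gvf(em, mu = 0.3, dt = 1), class = "param_error")
})

test_that("snake internal forces shorten a closed curve", {
  theta <- seq(0, 2 * pi, length.out = 11)[-11]
  poly <- nucleus_contour(cbind(30 + 10 * sin(theta) + runif(10),
                                30 + 10 * cos(theta)))
  field <- compute_gvf(matrix(0, 60, 60), n_iterations = 0)
  p <- snake_params(alpha = 0.2, beta = 0, gamma = 1, kappa = 0,
                    n_iterations = 1, resample_every = 0L)
  peri <- numeric(20)
  ct <- poly
  for (i in 1:20) {
    ct <- evolve_snake(ct, field, p)
    peri[i] <- rimfluct:::perimeter(ct)
  }
  expect_true(all(diff(c(rimfluct:::perimeter(poly), peri)) < 0))
})

test_that("a snake on a circular ridge is a fixed point", {
  # disk edge map: ridge on the circle of radius 20
  n <- 81
  yy <- matrix(1:n, n, n); xx <- t(yy)
  disk <- (sqrt((yy - 41)^2 + (xx - 41)^2) <= 20) * 100
  em <- edge_map(disk, sigma = 1.5)
  field <- compute_gvf(em, n_iterations = 60)
  # locate the ridge radius of the edge map along a ray from the center
  rr <- seq(15, 25, by = 0.05)
  ridge_r <- rr[which.max(rimfluct:::bilinear_sample(
    rimfluct:::as_matrix(em), rep(41, length(rr)), 41 + rr))]
  theta <- seq(0, 2 * pi, length.out = 121)[-121]
  circle <- nucleus_contour(cbind(41 + ridge_r * sin(theta),
                                  41 + ridge_r * cos(theta)))
  out <- evolve_snake(circle, field, snake_params(alpha = 0.05, beta = 0.1,
                                                  kappa = 2, n_iterations = 75))
  r <- sqrt((out[, 1] - 41)^2 + (out[, 2] - 41)^2)
  expect_lt(sqrt(mean((r - ridge_r)^2)), 0.5)
  expect_equal(nrow(out), 120)             # point count preserved
  expect_true(all(is.finite(out)))
  # zero iterations is the identity
  same <- evolve_snake(circle, field, snake_params(n_iterations = 0))
  expect_equal(unclass(same), unclass(circle), ignore_attr = TRUE)
})

test_that("full segmentation recovers the true ellipse boundary", {
  img <- generate_nucleus_image(synthetic_spec(seed = 11L))
  cts <- segment_nuclei(img$stack)
  expect_length(cts, 1)
  d <- contour_distance(cts[[1]], img$truth$contour)
  expect_lt(d$mean, 1)
  expect_lt(d$hausdorff, 2)
  # blank image yields an empty result with a warning
  blank <- image_stack(list(matrix(0, 32, 32), matrix(0, 32, 32)),
                       roles = c(counterstain = 1, reference = 2))
  expect_warning(res <- segment_nuclei(blank), "blank")
  expect_length(res, 0)
})
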