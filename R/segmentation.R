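#' Otsu threshold of an image
#'
#' Picks the histogram threshold maximizing the between-class variance of
#' foreground and background. Ties (flat stretches of the criterion, common
#' with few distinct values) resolve to the midpoint of the optimal run of
#' bin edges.
#'
#' @param image numeric matrix (or \code{image2d}).
#' @param n_bins number of histogram bins.
#' @return list with \code{threshold} (intensity units) and \code{mask}
#'   (logical matrix \code{image > threshold}, with the threshold attached
#'   as attribute \code{threshold_used}).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    rf_error("constant image has no separable classes", "degenerate_error")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  # exact per-bin value sums (not bin midpoints), so the maximized criterion
  # is the between-class variance of the actual data split at each bin edge
  sums <- numeric(n_bins)
  agg <- rowsum(x, bin)
  sums[as.integer(rownames(agg))] <- agg
  w0 <- cumsum(counts)
  m0 <- cumsum(sums)
  n <- w0[n_bins]; mtot <- m0[n_bins]
  # candidate thresholds are interior bin edges: split after bin k
  k <- seq_len(n_bins - 1)
  p0 <- w0[k] / n
  p1 <- 1 - p0
  mu0 <- ifelse(w0[k] > 0, m0[k] / w0[k], 0)
  mu1 <- ifelse(n - w0[k] > 0, (mtot - m0[k]) / (n - w0[k]), 0)
  sb <- p0 * p1 * (mu0 - mu1)^2
  best <- which(sb >= max(sb) - 1e-12 * max(1, max(sb)))
  thr <- mean(edges[best + 1])  # midpoint of the optimal edge run
  mask <- matrix(as.numeric(image) > thr, nrow(image), ncol(image))
  structure(list(threshold = thr,
                 mask = structure(mask, threshold_used = thr)),
            class = "otsu_result")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  m <- max(lab)
  if (m < 2) return(lab)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (sh[2] > 0) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] > 0) 2:nc else seq_len(nc - 1)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(m), find, 1L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Ordered closed contour
#'
#' An ordered closed sequence of sub-pixel (y, x) boundary points for one
#' nucleus; the last point connects implicitly to the first. Winding is
#' normalized so traversal is counter-clockwise in the (x right, y down)
#' image convention.
#'
#' @param pts numeric matrix, columns (y, x).
#' @return a \code{nucleus_contour} (matrix subclass).
#' @export
nucleus_contour <- function(pts) {
  pts <- as.matrix(pts)
  colnames(pts) <- c("y", "x")
  pts <- ensure_ccw(pts)
  structure(pts, class = c("nucleus_contour", "matrix", "array"),
            closed = TRUE)
}

#' @export
print.nucleus_contour <- function(x, ...) {
  cat(sprintf("nucleus_contour: %d points, perimeter %.1f px\n",
              nrow(x), perimeter(x)))
  invisible(x)
}

#' Initial nucleus boundaries from a binary mask
#'
#' Fills holes, labels 8-connected components, drops components below
#' \code{min_area}, and traces one ordered closed boundary per retained
#' component, arc-length resampled to \code{n_points}.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_area minimum component area in pixels.
#' @param n_points points per contour after resampling.
#' @return list of \code{nucleus_contour}.
#' @export
initial_boundary <- function(mask, min_area = 64, n_points = 200L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::fillHull(m)
  lab <- label_components8(m > 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep))
    rf_error("no components remain after min_area filtering", "degenerate_error")
  lab[!(lab %in% keep)] <- 0
  oc <- EBImage::ocontour(lab)
  oc <- oc[vapply(oc, nrow, 1L) >= 4]
  lapply(oc, function(pts) {
    # ocontour returns 0-based (row, col); shift to 1-based pixel centers
    nucleus_contour(resample_closed(pts + 1, n_points))
  })
}

#' Edge map of an image
#'
#' Gradient magnitude of the Gaussian-smoothed image, min-max normalized to
#' [0, 1] (all zeros for a constant image). This is the external-energy
#' input of the GVF snake.
#'
#' @param image numeric matrix.
#' @param sigma smoothing sigma in pixels (0 disables smoothing).
#' @return matrix in [0, 1] with attribute \code{smoothing_sigma}.
#' @export
edge_map <- function(image, sigma = 1.5) {
  if (sigma < 0) rf_error("sigma must be >= 0", "spec_error")
  g <- gaussian_blur(as_matrix(as.matrix(image)), sigma)
  gr <- gradient2d(g)
  mag <- sqrt(gr$gy^2 + gr$gx^2)
  rng <- range(mag)
  out <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
  structure(out, smoothing_sigma = sigma)
}

# Central-difference gradient with replicated borders.
gradient2d <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  gy <- (f[c(2:nr, nr), ] - f[c(1, 1:(nr - 1)), ]) / 2
  gx <- (f[, c(2:nc, nc)] - f[, c(1, 1:(nc - 1))]) / 2
  list(gy = gy, gx = gx)
}

laplacian2d <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  f[c(2:nr, nr), ] + f[c(1, 1:(nr - 1)), ] +
    f[, c(2:nc, nc)] + f[, c(1, 1:(nc - 1))] - 4 * f
}

#' Gradient vector field of an edge map
#'
#' Diffuses the edge-map gradient into homogeneous regions by iterating the
#' GVF evolution: the field follows the edge gradient where it is strong and
#' is a smooth interpolation elsewhere, extending the snake's capture range.
#'
#' @param edge edge map as from \code{\link{edge_map}}.
#' @param mu regularization (diffusion) weight.
#' @param dt time step; stability requires \code{mu * dt <= 0.25} on the
#'   unit pixel grid.
#' @param n_iterations diffusion iterations; 0 returns the raw gradient.
#' @return a \code{gvf_field}: list with components \code{vy}, \code{vx}
#'   and the parameters.
#' @export
compute_gvf <- function(edge, mu = 0.2, dt = 1, n_iterations = 80L) {
  if (mu * dt > 0.25)
    rf_error("unstable GVF parameters: need mu * dt <= 0.25", "param_error")
  f <- as_matrix(as.matrix(edge))
  gr <- gradient2d(f)
  fx <- gr$gx; fy <- gr$gy
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  for (i in seq_len(n_iterations)) {
    u <- u + dt * (mu * laplacian2d(u) - (u - fx) * b)
    v <- v + dt * (mu * laplacian2d(v) - (v - fy) * b)
  }
  if (!all(is.finite(u)) || !all(is.finite(v)))
    rf_error("GVF diverged to non-finite values", "param_error")
  structure(list(vy = v, vx = u, mu = mu, dt = dt,
                 n_iterations = as.integer(n_iterations)),
            class = "gvf_field")
}

#' Snake evolution parameters
#'
#' @param alpha tension (first-derivative) weight.
#' @param beta rigidity (second-derivative) weight.
#' @param gamma viscosity / implicit step weight.
#' @param kappa external (GVF) force weight.
#' @param n_iterations evolution iterations.
#' @param resample_every arc-length resample period in iterations (0 never;
#'   a final resample always restores uniform spacing).
#' @return a \code{snake_params} list.
#' @export
snake_params <- function(alpha = 0.4, beta = 0.5, gamma = 1, kappa = 2,
                         n_iterations = 75L, resample_every = 10L) {
  if (alpha < 0 || beta < 0 || gamma <= 0)
    rf_error("alpha, beta must be >= 0 and gamma > 0", "param_error")
  if (n_iterations < 0) rf_error("n_iterations must be >= 0", "param_error")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 n_iterations = as.integer(n_iterations),
                 resample_every = as.integer(resample_every)),
            class = "snake_params")
}

# Cyclic pentadiagonal internal-energy matrix for a closed snake.
snake_internal_matrix <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 2)] <- A[i, idx(i + 2)] <- beta
    A[i, idx(i - 1)] <- A[i, idx(i + 1)] <- -(alpha + 4 * beta)
    A[i, i] <- 2 * alpha + 6 * beta
  }
  A
}

#' Evolve a parametric snake under a GVF external force
#'
#' Semi-implicit evolution of a closed active contour: tension and rigidity
#' are solved implicitly on the cyclic pentadiagonal system, the external
#' force is the GVF sampled bilinearly at the (sub-pixel) snake points.
#' Point count is preserved; the contour is arc-length resampled every
#' \code{resample_every} iterations and after the last one.
#'
#' @param contour a \code{nucleus_contour}.
#' @param field a \code{gvf_field}.
#' @param params a \code{snake_params}.
#' @return the evolved \code{nucleus_contour}.
#' @export
evolve_snake <- function(contour, field, params = snake_params()) {
  pts <- unclass(contour)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (params$n_iterations == 0L) return(nucleus_contour(pts))
  nr <- nrow(field$vy); nc <- ncol(field$vy)
  A <- snake_internal_matrix(n, params$alpha, params$beta)
  M <- solve(params$gamma * diag(n) + A)
  y <- pts[, 1]; x <- pts[, 2]
  escaped <- FALSE
  for (it in seq_len(params$n_iterations)) {
    fy <- bilinear_sample(field$vy, y, x)
    fx <- bilinear_sample(field$vx, y, x)
    y <- as.numeric(M %*% (params$gamma * y + params$kappa * fy))
    x <- as.numeric(M %*% (params$gamma * x + params$kappa * fx))
    if (any(y < 1 | y > nr | x < 1 | x > nc)) {
      escaped <- TRUE
      y <- pmin(pmax(y, 1), nr); x <- pmin(pmax(x, 1), nc)
    }
    if (!all(is.finite(y)) || !all(is.finite(x)))
      rf_error("snake produced non-finite coordinates", "param_error")
    if (params$resample_every > 0 &&
        (it %% params$resample_every == 0L || it == params$n_iterations)) {
      rs <- resample_closed(cbind(y, x), n)
      y <- rs[, 1]; x <- rs[, 2]
    }
  }
  if (params$resample_every == 0L) {
    rs <- resample_closed(cbind(y, x), n)
    y <- rs[, 1]; x <- rs[, 2]
  }
  if (escaped) warning("snake points left the image frame and were clamped")
  nucleus_contour(cbind(y, x))
}

#' Segmentation configuration
#'
#' Defaults for the two-step segmentation: Otsu initial boundary on the
#' counterstain projection, GVF snake refinement. The edge map driving the
#' snake defaults to the counterstain channel, whose blurred step edge puts
#' the gradient maximum exactly on the nuclear boundary; the rim-shaped
#' reference channel can be selected instead (\code{edge_channel =
#' "reference"}) but its gradient magnitude vanishes on the rim centerline,
#' biasing the converged contour toward the rim flanks.
#'
#' @param n_bins Otsu histogram bins.
#' @param min_area minimum nucleus area, pixels.
#' @param n_points snake points per contour.
#' @param edge_channel channel role driving the edge map.
#' @param edge_sigma edge-map smoothing sigma, pixels.
#' @param mu,dt,gvf_iterations GVF parameters.
#' @param snake a \code{snake_params}.
#' @return a config list.
#' @export
segment_config <- function(n_bins = 256L, min_area = 200, n_points = 200L,
                           edge_channel = "counterstain", edge_sigma = 1.5,
                           mu = 0.2, dt = 1, gvf_iterations = 80L,
                           snake = snake_params()) {
  list(n_bins = n_bins, min_area = min_area, n_points = n_points,
       edge_channel = edge_channel, edge_sigma = edge_sigma,
       mu = mu, dt = dt, gvf_iterations = gvf_iterations, snake = snake)
}

#' Segment nuclei in a multi-channel stack
#'
#' Full two-step pipeline: maximum-intensity projections, Otsu threshold of
#' the counterstain, hole-filled 8-connected components and boundary
#' tracing, then GVF active-contour refinement (75 iterations by default).
#'
#' @param stack an \code{image_stack} with at least counterstain and
#'   reference roles.
#' @param config a \code{\link{segment_config}} list.
#' @return list of refined \code{nucleus_contour} (possibly empty, with a
#'   warning, for blank images).
#' @export
segment_nuclei <- function(stack, config = segment_config()) {
  require_roles(stack, c("counterstain", "reference"))
  counter <- max_intensity_projection(stack, "counterstain")
  res <- tryCatch(otsu_threshold(counter, n_bins = config$n_bins),
                  degenerate_error = function(e) NULL)
  if (is.null(res)) {
    warning("blank (constant) counterstain image; no nuclei found")
    return(list())
  }
  contours <- tryCatch(
    initial_boundary(res$mask, min_area = config$min_area,
                     n_points = config$n_points),
    degenerate_error = function(e) NULL)
  if (is.null(contours)) {
    warning("no nuclei above min_area")
    return(list())
  }
  edge_img <- max_intensity_projection(stack, config$edge_channel)
  em <- edge_map(edge_img, sigma = config$edge_sigma)
  field <- compute_gvf(em, mu = config$mu, dt = config$dt,
                       n_iterations = config$gvf_iterations)
  lapply(contours, evolve_snake, field = field, params = config$snake)
}
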