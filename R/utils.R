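# Internal numerical helpers shared across modules.
# Coordinate convention (package-wide): matrices are indexed [row = y, col = x],
# 1-based, coordinates refer to pixel centers; sub-pixel positions are real
# numbers on that grid.

rf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rimfluct_error")))
}

#' Bilinear interpolation of an image at sub-pixel positions
#'
#' @param img numeric matrix indexed \code{[y, x]}.
#' @param y,x numeric vectors of equal length; 1-based pixel-center
#'   coordinates. Coordinates are clamped to the image frame.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, y, x) {
  nr <- nrow(img); nc <- ncol(img)
  y <- pmin(pmax(y, 1), nr)
  x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Signed area of a closed polygon given as (y, x) rows; positive means
# counter-clockwise in the (x right, y down) image convention used here.
signed_area <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  -0.5 * sum(x * yn - xn * y)
}

ensure_ccw <- function(pts) {
  if (signed_area(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

perimeter <- function(pts) {
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

# Resample a closed polygon to n points equally spaced in arc length.
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(pts[rep(1, n), , drop = FALSE])
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  yi <- stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y
  xi <- stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y
  cbind(yi, xi, deparse.level = 0)
}

# Min distance from each point in P (rows of (y, x)) to the closed polyline Q.
points_to_polyline <- function(P, Q) {
  Qc <- rbind(Q, Q[1, , drop = FALSE])
  a <- Qc[-nrow(Qc), , drop = FALSE]
  d <- Qc[-1, , drop = FALSE] - a
  len2 <- rowSums(d^2)
  len2[len2 == 0] <- 1e-300
  apply(P, 1, function(p) {
    t <- ((p[1] - a[, 1]) * d[, 1] + (p[2] - a[, 2]) * d[, 2]) / len2
    t <- pmin(pmax(t, 0), 1)
    proj_y <- a[, 1] + t * d[, 1]
    proj_x <- a[, 2] + t * d[, 2]
    sqrt(min((p[1] - proj_y)^2 + (p[2] - proj_x)^2))
  })
}

#' Contour distance metrics against a reference curve
#'
#' Mean and maximum (Hausdorff) distance between two closed contours,
#' computed symmetrically point-to-segment in both directions.
#'
#' @param contour,reference matrices of (y, x) points on closed curves.
#' @return list with \code{mean} and \code{hausdorff} distances in pixels.
#' @export
contour_distance <- function(contour, reference) {
  d1 <- points_to_polyline(contour, reference)
  d2 <- points_to_polyline(reference, contour)
  list(mean = mean(c(d1, d2)), hausdorff = max(c(d1, d2)))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}
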