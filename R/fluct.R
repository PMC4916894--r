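#' Intensity profile along a contour or line
#'
#' @param values numeric intensities in traversal order.
#' @param positions matrix of (y, x) source coordinates.
#' @param circular TRUE for closed-contour profiles.
#' @return an \code{intensity_profile}.
#' @export
intensity_profile <- function(values, positions = NULL, circular = TRUE) {
  if (!all(is.finite(values))) rf_error("profile values must be finite", "profile_error")
  if (circular && length(values) < 4)
    rf_error("circular profiles need at least 4 samples", "profile_error")
  structure(list(values = as.numeric(values), positions = positions,
                 circular = isTRUE(circular)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: %d %s samples, range [%.3g, %.3g]\n",
              length(x$values), if (x$circular) "circular" else "linear",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample channel intensities along a contour
#'
#' Bilinear interpolation of the image at each (sub-pixel) contour point,
#' in traversal order. With \code{quantize = TRUE} (the default) the
#' interpolated values are rounded back to integer counts: the quantified
#' signal is the pixel intensity, an integer in camera-exported data, and
#' preserving that integer resolution is what lets flat dim stretches of a
#' punctate channel register an exactly-zero derivative (the divide-by-zero
#' correction then pins those positions at the ratio maximum, which is the
#' index's sensitivity to punctate gaps).
#'
#' @param image numeric matrix (a channel projection).
#' @param contour a \code{nucleus_contour}.
#' @param quantize round sampled values to integer counts.
#' @return a circular \code{intensity_profile}.
#' @export
sample_contour_intensity <- function(image, contour, quantize = TRUE) {
  y <- contour[, 1]; x <- contour[, 2]
  if (any(y < 1 | y > nrow(image) | x < 1 | x > ncol(image)))
    rf_error("contour points fall outside the image", "geometry_error")
  v <- bilinear_sample(as_matrix(as.matrix(image)), y, x)
  if (quantize) v <- round(v)
  intensity_profile(v, positions = cbind(y, x), circular = TRUE)
}

#' Circular first derivative of a profile
#'
#' Central differences with wraparound: \code{d[i] = (v[i+1] - v[i-1]) / 2},
#' indices modulo the profile length. The derivative of any closed profile
#' sums to zero.
#'
#' @param profile a circular \code{intensity_profile}.
#' @return numeric vector of derivatives.
#' @export
circular_derivative <- function(profile) {
  if (!inherits(profile, "intensity_profile") || !profile$circular)
    rf_error("circular_derivative requires a circular profile", "contract_error")
  v <- profile$values
  n <- length(v)
  if (n < 3) rf_error("profile too short for a derivative", "contract_error")
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / 2
}

#' Normalize a signal
#'
#' \code{max_abs} divides by the maximum absolute value (used on the
#' derivative stage); \code{min_max} maps linearly onto [0, 1] (used on the
#' ratio stage). A constant array maps to all zeros in both modes — the
#' degenerate rule that anchors the identical-pattern case to index 0.
#'
#' @param values numeric vector.
#' @param mode \code{"max_abs"} or \code{"min_max"}.
#' @return normalized numeric vector.
#' @export
normalize_signal <- function(values, mode = c("max_abs", "min_max")) {
  mode <- match.arg(mode)
  if (!all(is.finite(values))) rf_error("values must be finite", "profile_error")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  if (mode == "max_abs") values / max(abs(values))
  else (values - rng[1]) / (rng[2] - rng[1])
}

# Per-position ratio of derivative magnitudes num/den with the divide-by-zero
# rule: 0/0 -> 1 (both channels flat: locally identical behavior, the ratio
# of an identical pair); x/0 (x > 0) -> the maximum finite ratio in this
# direction (1 if no finite ratio exists). The 0/0 -> 1 choice makes the
# identity fluctuation_index(p, p) = 0 exact for EVERY profile p: the ratio
# array of an identical pair is then constant, and the min-max stage maps
# any constant array to zeros.
ratio_with_correction <- function(num, den) {
  r <- rep(1, length(num))
  ok <- den > 0
  r[ok] <- num[ok] / den[ok]
  bad <- !ok & num > 0
  if (any(bad)) r[bad] <- if (any(ok)) max(r[ok]) else 1
  r
}

#' Fluctuation index of a test channel against a reference channel
#'
#' The per-nucleus punctateness statistic. From intensity profiles sampled
#' at the same contour points in the reference (e.g. lamin B) and test
#' (e.g. lamin A/C or prelamin A) channels:
#' \enumerate{
#'   \item the circular first derivative of each profile is computed and
#'     normalized by its maximum absolute value;
#'   \item per-position ratios of the derivative magnitudes are formed in
#'     both directions (reference/test and test/reference) with
#'     divide-by-zero correction, and each ratio array is min-max
#'     normalized to [0, 1];
#'   \item the fraction of positions with normalized ratio above
#'     \code{threshold} is expressed as a percentage for each direction and
#'     the two percentages are added.
#' }
#' A test channel whose spatial pattern along the envelope is identical to
#' the reference yields index 0; the index grows as the test signal becomes
#' increasingly punctate, up to a maximum of 200.
#'
#' @param ref,test circular \code{intensity_profile}s of equal length
#'   sampled on the same contour.
#' @param threshold ratio threshold (default 0.15).
#' @return a \code{fluctuation_result}: \code{index},
#'   \code{fraction_12}/\code{fraction_21} (percentages per direction),
#'   the normalized derivative and ratio arrays, and the threshold.
#' @export
fluctuation_index <- function(ref, test, threshold = 0.15) {
  if (!inherits(ref, "intensity_profile") || !inherits(test, "intensity_profile"))
    rf_error("ref and test must be intensity_profile objects", "contract_error")
  if (!ref$circular || !test$circular)
    rf_error("fluctuation_index requires circular profiles", "contract_error")
  n <- length(ref$values)
  if (length(test$values) != n)
    rf_error("ref and test profiles differ in length", "contract_error")
  if (n < 8)
    rf_error("fewer than 8 positions; the metric is unstable", "contract_error")
  d_ref  <- normalize_signal(circular_derivative(ref),  "max_abs")
  d_test <- normalize_signal(circular_derivative(test), "max_abs")
  a <- abs(d_ref); b <- abs(d_test)
  ratio_12 <- normalize_signal(ratio_with_correction(a, b), "min_max")
  ratio_21 <- normalize_signal(ratio_with_correction(b, a), "min_max")
  fraction_12 <- 100 * mean(ratio_12 > threshold)
  fraction_21 <- 100 * mean(ratio_21 > threshold)
  structure(list(index = fraction_12 + fraction_21,
                 fraction_12 = fraction_12, fraction_21 = fraction_21,
                 derivative_ref = d_ref, derivative_test = d_test,
                 ratio_12 = ratio_12, ratio_21 = ratio_21,
                 threshold = threshold, n_points = n),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf(paste0("fluctuation_result: index %.2f ",
                     "(ref/test %.2f%% + test/ref %.2f%%), %d points, ",
                     "threshold %.2f\n"),
              x$index, x$fraction_12, x$fraction_21, x$n_points, x$threshold))
  invisible(x)
}

#' Linescan intensity profiles across a line segment
#'
#' Bilinear samples at evenly spaced points on the segment from \code{p0}
#' to \code{p1} in each channel, each channel scaled so its maximum reads
#' 100 (a constant channel reads all 100; an all-zero channel reads 0).
#'
#' @param images list of numeric matrices (channels).
#' @param p0,p1 segment endpoints as c(y, x).
#' @param n_samples number of samples along the segment.
#' @return list of linear \code{intensity_profile}s, one per channel.
#' @export
linescan_profile <- function(images, p0, p1, n_samples = 100L) {
  if (all(p0 == p1)) rf_error("degenerate segment: p0 equals p1", "geometry_error")
  t <- seq(0, 1, length.out = n_samples)
  y <- p0[1] + t * (p1[1] - p0[1])
  x <- p0[2] + t * (p1[2] - p0[2])
  lapply(images, function(img) {
    img <- as_matrix(as.matrix(img))
    if (any(y < 1 | y > nrow(img) | x < 1 | x > ncol(img)))
      rf_error("linescan endpoints outside the image", "geometry_error")
    v <- bilinear_sample(img, y, x)
    m <- max(v)
    v <- if (m > 0) 100 * v / m else v
    intensity_profile(v, positions = cbind(y, x), circular = FALSE)
  })
}
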