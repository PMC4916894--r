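#' Specification of a synthetic rim-labeled nucleus image
#'
#' Parameterizes a three-channel 2D field emulating a deconvolved
#' fluorescence image of one nucleus: a counterstain channel (filled
#' elliptical interior, DAPI role), a reference envelope channel with a
#' spatially continuous rim (lamin B role), and a test channel whose rim
#' signal is a mixture of a continuous baseline and discrete angular foci
#' (lamin A/C or prelamin A role).
#'
#' The rim is a Gaussian profile normal to the ellipse boundary. Along the
#' boundary the test-channel intensity is
#' \deqn{w(\phi) = f_b + (1 - f_b)\, c \sum_k \exp(-\Delta(\phi,\phi_k)^2 / 2\sigma_f^2)}
#' with \eqn{f_b} = \code{baseline_fraction}, \eqn{c} = \code{focus_contrast},
#' \eqn{\sigma_f} = \code{focus_arc_sigma}, and \eqn{\Delta} the wrapped
#' angular difference; \eqn{w} is rescaled so its maximum equals
#' \code{rim_amplitude}. Both rim channels are additionally multiplied by a
#' shared smooth angular brightness field (low-order harmonics of amplitude
#' \code{envelope_modulation}), emulating the envelope-intensity variation
#' real lamin rims show along the contour; because it is shared, it cancels
#' in relative-fluctuation comparisons. With \code{n_foci = 0} and
#' \code{baseline_fraction = 1} the test channel reproduces the reference
#' channel's spatial pattern exactly.
#'
#' The noise model emulates deconvolved high-SNR imagery: per-pixel shot
#' noise (variance \code{poisson_scale} times intensity) plus read noise
#' (\code{gaussian_sd}), spatially smoothed over \code{residual_sigma}
#' pixels — deconvolution leaves low-amplitude, spatially correlated
#' residual noise rather than white camera noise. With
#' \code{quantize = TRUE} the final image is rounded to integer counts like
#' a 16-bit export.
#'
#' @param image_size c(H, W) pixels.
#' @param center c(y, x) ellipse center, pixels (sub-pixel allowed).
#' @param semi_axes c(a, b) semi-axes, pixels; a lies along \code{orientation}.
#' @param orientation radians.
#' @param rim_width Gaussian sigma of the rim profile normal to the boundary,
#'   pixels.
#' @param rim_amplitude peak rim intensity (counts) of the reference and test
#'   channels.
#' @param counterstain_amplitude interior intensity of the counterstain.
#' @param n_foci number of discrete foci in the test channel.
#' @param focus_arc_sigma angular extent (sigma) of each focus, radians.
#' @param focus_contrast ratio of focus peak to the continuous baseline.
#' @param baseline_fraction continuous rim component of the test channel,
#'   in [0, 1].
#' @param focus_placement \code{"random"} (uniform angles, seeded) or
#'   \code{"spaced"} (equally spaced).
#' @param envelope_modulation amplitude (relative sd) of the shared smooth
#'   angular brightness variation of the rim, dimensionless.
#' @param test_own_modulation amplitude of an additional smooth angular
#'   variation applied to the test channel only (independent harmonic
#'   draw), emulating a homogeneous protein whose distribution tracks the
#'   envelope without being a pixel copy of the reference. 0 (default)
#'   keeps the test channel's pattern exactly proportional to the
#'   reference when \code{n_foci = 0} and \code{baseline_fraction = 1}.
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param noise \code{"none"}, or a list with \code{gaussian_sd} (read noise,
#'   counts), \code{poisson_scale} (shot-noise variance per intensity count;
#'   0 disables shot noise) and \code{residual_sigma} (spatial correlation
#'   length of the residual noise, pixels; 0 gives white noise).
#' @param background constant offset, counts.
#' @param quantize round the final image to integer counts.
#' @param seed integer; together with the other fields it determines the
#'   image bit-for-bit.
#' @return a \code{synthetic_spec} object.
#' @export
synthetic_spec <- function(image_size = c(128, 128),
                           center = c(64.3, 63.6),
                           semi_axes = c(38, 27),
                           orientation = 0.4,
                           rim_width = 1.5,
                           rim_amplitude = 3000,
                           counterstain_amplitude = 2000,
                           n_foci = 0,
                           focus_arc_sigma = 0.12,
                           focus_contrast = 0,
                           baseline_fraction = 1,
                           focus_placement = c("random", "spaced"),
                           envelope_modulation = 0.25,
                           test_own_modulation = 0,
                           psf_sigma = 1,
                           noise = list(gaussian_sd = 0.2, poisson_scale = 0.02,
                                        residual_sigma = 2.5),
                           background = 100,
                           quantize = TRUE,
                           seed = 1L) {
  if (identical(noise, "none"))
    noise <- list(gaussian_sd = 0, poisson_scale = 0, residual_sigma = 0)
  spec <- structure(list(
    image_size = as.numeric(image_size), center = as.numeric(center),
    semi_axes = as.numeric(semi_axes), orientation = orientation,
    rim_width = rim_width, rim_amplitude = rim_amplitude,
    counterstain_amplitude = counterstain_amplitude,
    n_foci = as.integer(n_foci), focus_arc_sigma = focus_arc_sigma,
    focus_contrast = focus_contrast, baseline_fraction = baseline_fraction,
    focus_placement = match.arg(focus_placement),
    envelope_modulation = envelope_modulation,
    test_own_modulation = test_own_modulation,
    psf_sigma = psf_sigma, noise = noise, background = background,
    quantize = isTRUE(quantize),
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (any(spec$semi_axes <= 0))
    rf_error("semi_axes must be strictly positive", "geometry_error")
  if (spec$baseline_fraction < 0 || spec$baseline_fraction > 1)
    rf_error("baseline_fraction must be in [0, 1]", "spec_error")
  if (spec$n_foci < 0) rf_error("n_foci must be >= 0", "spec_error")
  if (spec$focus_contrast < 0) rf_error("focus_contrast must be >= 0", "spec_error")
  support <- 3 * (spec$rim_width + spec$psf_sigma)
  r <- max(spec$semi_axes) + support
  if (spec$center[1] - r < 1 || spec$center[1] + r > spec$image_size[1] ||
      spec$center[2] - r < 1 || spec$center[2] + r > spec$image_size[2])
    rf_error("ellipse plus rim support exceeds the image frame", "geometry_error")
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: %dx%d px, axes (%.1f, %.1f), ",
                     "%d foci (contrast %.2g, baseline %.2g), seed %d\n"),
              x$image_size[1], x$image_size[2], x$semi_axes[1], x$semi_axes[2],
              x$n_foci, x$focus_contrast, x$baseline_fraction, x$seed))
  invisible(x)
}

# Wrapped angular difference in [-pi, pi].
ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# Deterministic focus angles for a spec (consumes its own seeded stream).
focus_angles_for <- function(spec) {
  if (spec$n_foci == 0) return(numeric(0))
  if (spec$focus_placement == "spaced") {
    (2 * pi * (seq_len(spec$n_foci) - 1) / spec$n_foci + 0.7) %% (2 * pi)
  } else {
    withr::with_seed(spec$seed, stats::runif(spec$n_foci, 0, 2 * pi))
  }
}

# Unnormalized along-boundary weight of the test channel at angles phi.
angular_weight <- function(phi, spec, focus_angles) {
  w <- rep(spec$baseline_fraction, length(phi))
  if (length(focus_angles)) {
    bump <- 0
    for (fa in focus_angles)
      bump <- bump + exp(-ang_diff(phi, fa)^2 / (2 * spec$focus_arc_sigma^2))
    w <- w + (1 - spec$baseline_fraction) * spec$focus_contrast * bump
  }
  w
}

# Smooth angular brightness field: low-order harmonics with seeded
# coefficients, scaled so its relative sd equals `amplitude`, clamped
# positive. `salt` decorrelates independent fields drawn from one spec seed.
harmonic_field <- function(seed, amplitude, salt) {
  if (amplitude <= 0) return(function(phi) rep(1, length(phi)))
  coef <- withr::with_seed(bitwXor(seed, salt), stats::rnorm(8))
  function(phi) {
    s <- rep(0, length(phi))
    for (k in 1:4)
      s <- s + coef[2 * k - 1] * cos(k * phi) + coef[2 * k] * sin(k * phi)
    # each unit-coefficient harmonic contributes variance 1/2
    pmax(1 + amplitude * s / sqrt(sum(coef^2) / 2), 0.05)
  }
}

envelope_field_for <- function(spec)
  harmonic_field(spec$seed, spec$envelope_modulation, 192837465L)

test_field_for <- function(spec)
  harmonic_field(spec$seed, spec$test_own_modulation, 55443322L)

#' Noiseless along-boundary rim intensity of the test channel
#'
#' The analytic test-channel rim intensity as a function of boundary angle,
#' before point-spread blur and noise (focal pattern times the shared
#' envelope brightness field). Useful for calibrating punctateness: its
#' coefficient of variation grows with \code{focus_contrast}.
#'
#' @param spec a \code{synthetic_spec}.
#' @param n number of equally spaced boundary angles.
#' @return list with \code{phi} (angles) and \code{intensity} (counts).
#' @export
rim_angular_profile <- function(spec, n = 1024) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  fa <- focus_angles_for(spec)
  w <- angular_weight(phi, spec, fa)
  dense <- angular_weight(seq(0, 2 * pi, length.out = 4096), spec, fa)
  m <- max(dense)
  if (m <= 0) return(list(phi = phi, intensity = rep(0, n)))
  env <- envelope_field_for(spec)
  list(phi = phi, intensity = spec$rim_amplitude * env(phi) * w / m)
}

#' Generate a synthetic nucleus image with ground truth
#'
#' Renders the three channels analytically on the pixel grid (intensities
#' evaluated at pixel centers), convolves with a Gaussian PSF, adds
#' background, and applies Poisson (shot) and Gaussian (read) noise.
#' Identical specs produce bit-identical images.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{stack} (an \code{image_stack} with roles
#'   counterstain/reference/test) and \code{truth} (a \code{ground_truth}:
#'   densely sampled true contour, boundary angles, focus angles, spec).
#' @export
generate_nucleus_image <- function(spec) {
  validate_spec(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  th <- spec$orientation
  dy <- yy - spec$center[1]; dx <- xx - spec$center[2]
  u <-  cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  rho <- sqrt((u / a)^2 + (v / b)^2)
  # first-order signed distance to the ellipse: (rho - 1) / |grad rho|
  gradrho <- sqrt(u^2 / a^4 + v^2 / b^4) / pmax(rho, 1e-9)
  delta <- ifelse(rho < 1e-9, -min(a, b), (rho - 1) / pmax(gradrho, 1e-9))
  phi <- atan2(v / b, u / a)

  rim_shape <- exp(-delta^2 / (2 * spec$rim_width^2))
  env <- envelope_field_for(spec)(phi)
  dim(env) <- c(H, W)
  reference <- spec$rim_amplitude * env * rim_shape

  fa <- focus_angles_for(spec)
  w <- angular_weight(phi, spec, fa)
  wmax <- max(angular_weight(seq(0, 2 * pi, length.out = 4096), spec, fa))
  wn <- if (wmax > 0) w / wmax else w * 0
  own <- test_field_for(spec)(phi)
  dim(own) <- c(H, W)
  test <- spec$rim_amplitude * env * own * wn * rim_shape

  # soft-edged uniform interior so the counterstain histogram is bimodal
  counterstain <- spec$counterstain_amplitude * stats::plogis(-delta / 0.5)

  channels <- list(counterstain = counterstain, reference = reference,
                   test = test)
  channels <- lapply(channels, gaussian_blur, sigma = spec$psf_sigma)
  channels <- lapply(channels, function(ch) ch + spec$background)

  noise <- spec$noise
  gsd <- if (is.null(noise$gaussian_sd)) 0 else noise$gaussian_sd
  psc <- if (is.null(noise$poisson_scale)) 0 else noise$poisson_scale
  rsig <- if (is.null(noise$residual_sigma)) 0 else noise$residual_sigma
  # separate stream from the focus-angle draw; xor keeps it a valid 32-bit int
  noise_seed <- bitwXor(spec$seed, 87654321L)
  channels <- withr::with_seed(noise_seed, {
    lapply(channels, function(ch) {
      if (gsd > 0 || psc > 0) {
        # shot + read noise, spatially correlated over residual_sigma as
        # left by deconvolution (white if residual_sigma = 0)
        z <- matrix(stats::rnorm(H * W), H, W)
        if (rsig > 0) {
          z <- gaussian_blur(z, rsig)
          z <- z / stats::sd(z)
        }
        ch <- ch + z * sqrt(psc * pmax(ch, 0) + gsd^2)
      }
      ch
    })
  })
  if (spec$quantize)
    channels <- lapply(channels, function(ch) pmax(round(ch), 0))

  stack <- image_stack(channels,
                       roles = c(counterstain = 1L, reference = 2L, test = 3L))
  t_dense <- seq(0, 2 * pi, length.out = 1441)[-1441]
  cy <- spec$center[1] + a * cos(t_dense) * sin(th) + b * sin(t_dense) * cos(th)
  cx <- spec$center[2] + a * cos(t_dense) * cos(th) - b * sin(t_dense) * sin(th)
  pts <- cbind(cy, cx, deparse.level = 0)
  if (signed_area(pts) < 0) {           # keep angles aligned with the
    rev_idx <- rev(seq_len(nrow(pts)))  # winding-normalized point order
    pts <- pts[rev_idx, , drop = FALSE]
    t_dense <- t_dense[rev_idx]
  }
  truth <- structure(list(
    contour = nucleus_contour(pts),
    boundary_angles = t_dense, focus_angles = fa, spec = spec),
    class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Generate the three-case calibration series
#'
#' Reproduces the simulated-measurement calibration of the fluctuation
#' index: Case 1 has a test channel whose spatial pattern is identical to
#' the reference (index 0), Case 2 has moderate puncta, and Case 3 strong
#' puncta; indices are nondecreasing across the series. Only the
#' punctateness parameters (\code{n_foci}, \code{focus_contrast},
#' \code{baseline_fraction}) differ between cases; geometry, noise and seed
#' are shared. The default base spec is noiseless, as befits calibration.
#'
#' @param base_spec the shared \code{synthetic_spec}.
#' @param case_params list of three lists overriding the punctateness
#'   fields per case.
#' @return list of three \code{list(stack, truth)} elements, named
#'   \code{case1..case3}.
#' @export
generate_case_series <- function(base_spec = synthetic_spec(noise = "none"),
                                 case_params = list(
                                   case1 = list(n_foci = 0L, focus_contrast = 0,
                                                baseline_fraction = 1),
                                   case2 = list(n_foci = 6L, focus_contrast = 2,
                                                baseline_fraction = 0.5),
                                   case3 = list(n_foci = 6L, focus_contrast = 8,
                                                baseline_fraction = 0.05))) {
  stopifnot(length(case_params) == 3)
  allowed <- c("n_foci", "focus_contrast", "baseline_fraction")
  out <- lapply(case_params, function(p) {
    stopifnot(all(names(p) %in% allowed))
    spec <- base_spec
    for (nm in names(p)) spec[[nm]] <- p[[nm]]
    spec$n_foci <- as.integer(spec$n_foci)
    generate_nucleus_image(spec)
  })
  names(out) <- names(case_params)
  out
}

#' Generate a two-group cohort of synthetic nuclei
#'
#' Draws \code{n_per_group} nuclei per group with jittered geometry
#' (center, semi-axes, orientation), one group from each spec; only the
#' punctateness parameters should differ between the two specs. Fully
#' deterministic given \code{seed}.
#'
#' @param spec_punctate spec for the punctate group (default: 10 strong foci
#'   over a dim continuous baseline).
#' @param spec_uniform spec for the uniform group (default: continuous rim).
#' @param n_per_group nuclei per group.
#' @param seed integer master seed for jitter and per-image noise seeds.
#' @return list of entries \code{list(stack, truth, label, id)}; labels are
#'   \code{"punctate"} and \code{"uniform"}.
#' @export
generate_cohort <- function(spec_punctate = synthetic_spec(
                              n_foci = 6L, focus_contrast = 5,
                              baseline_fraction = 0.05,
                              test_own_modulation = 0.15),
                            spec_uniform = synthetic_spec(
                              test_own_modulation = 0.15),
                            n_per_group = 44L, seed = 1L) {
  if (n_per_group < 1) rf_error("n_per_group must be >= 1", "spec_error")
  n <- 2L * as.integer(n_per_group)
  jit <- withr::with_seed(as.integer(seed), list(
    dcy = stats::runif(n, -3, 3), dcx = stats::runif(n, -3, 3),
    fa = stats::runif(n, 0.85, 1.15), fb = stats::runif(n, 0.85, 1.15),
    th = stats::runif(n, 0, pi),
    child = sample.int(.Machine$integer.max - 1L, n)))
  labels <- rep(c("punctate", "uniform"), each = n_per_group)
  base <- list(punctate = spec_punctate, uniform = spec_uniform)
  lapply(seq_len(n), function(i) {
    spec <- base[[labels[i]]]
    spec$center <- spec$center + c(jit$dcy[i], jit$dcx[i])
    spec$semi_axes <- spec$semi_axes * c(jit$fa[i], jit$fb[i])
    spec$orientation <- jit$th[i]
    spec$seed <- jit$child[i]
    img <- generate_nucleus_image(spec)
    list(stack = img$stack, truth = img$truth, label = labels[i],
         id = sprintf("%s_%02d", labels[i],
                      ((i - 1L) %% n_per_group) + 1L))
  })
}

#' Write a synthetic image and its ground truth to disk
#'
#' Writes a multi-page TIFF (one page per channel) and a YAML sidecar
#' recording the generating spec, the channel roles, the focus angles and
#' the true contour points.
#'
#' @param img a \code{list(stack, truth)} as from
#'   \code{\link{generate_nucleus_image}}.
#' @param path output TIFF path; the sidecar gets extension \code{.yaml}.
#' @param bits TIFF bit depth (8 or 16).
#' @return \code{path}, invisibly.
#' @export
write_synthetic_image <- function(img, path, bits = 16L) {
  write_stack(img$stack, path, bits = bits)
  spec <- img$truth$spec
  spec$focus_placement <- as.character(spec$focus_placement)
  sidecar <- list(
    spec = unclass(spec),
    channel_roles = as.list(img$stack$roles),
    focus_angles = as.numeric(img$truth$focus_angles),
    contour = list(y = as.numeric(img$truth$contour[, 1]),
                   x = as.numeric(img$truth$contour[, 2])))
  yaml::write_yaml(sidecar, sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE))
  invisible(path)
}

#' Read a synthetic image written by \code{write_synthetic_image}
#'
#' @param path TIFF path with a YAML sidecar next to it.
#' @return list with \code{stack} and \code{truth} (contour and focus angles
#'   restored from the sidecar).
#' @export
read_synthetic_image <- function(path) {
  sidecar <- yaml::read_yaml(sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE))
  roles <- unlist(sidecar$channel_roles)
  stack <- read_stack(path, role_map = roles)
  truth <- structure(list(
    contour = nucleus_contour(cbind(sidecar$contour$y, sidecar$contour$x,
                                    deparse.level = 0)),
    focus_angles = as.numeric(sidecar$focus_angles),
    spec = sidecar$spec), class = "ground_truth")
  list(stack = stack, truth = truth)
}
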