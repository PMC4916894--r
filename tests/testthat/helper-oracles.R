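# Independent oracles, written as literal step-by-step loop code so they
# share no implementation with the package functions they check.

# Literal three-step fluctuation index: circular central differences,
# max-abs normalization, bidirectional magnitude ratios with divide-by-zero
# correction (0/0 -> 1, x/0 -> max finite ratio), min-max to [0, 1]
# (constant -> zeros), percentage of positions above the threshold, summed.
oracle_fluctuation_index <- function(ref, test, threshold = 0.15) {
  n <- length(ref)
  deriv <- function(v) {
    d <- numeric(n)
    for (i in seq_len(n)) {
      ip <- if (i == n) 1L else i + 1L
      im <- if (i == 1L) n else i - 1L
      d[i] <- (v[ip] - v[im]) / 2
    }
    d
  }
  maxabs <- function(d) {
    m <- max(abs(d))
    if (max(d) == min(d)) return(numeric(n))
    d / m
  }
  a <- abs(maxabs(deriv(ref)))
  b <- abs(maxabs(deriv(test)))
  one_direction <- function(num, den) {
    r <- numeric(n)
    finite_max <- -Inf
    for (i in seq_len(n)) if (den[i] > 0) {
      r[i] <- num[i] / den[i]
      if (r[i] > finite_max) finite_max <- r[i]
    }
    if (!is.finite(finite_max)) finite_max <- 1
    for (i in seq_len(n)) {
      if (den[i] == 0 && num[i] == 0) r[i] <- 1
      if (den[i] == 0 && num[i] > 0) r[i] <- finite_max
    }
    lo <- min(r); hi <- max(r)
    if (hi == lo) r <- numeric(n) else r <- (r - lo) / (hi - lo)
    count <- 0
    for (i in seq_len(n)) if (r[i] > threshold) count <- count + 1
    100 * count / n
  }
  f12 <- one_direction(a, b)
  f21 <- one_direction(b, a)
  list(index = f12 + f21, fraction_12 = f12, fraction_21 = f21)
}

# Exhaustive Otsu: try every interior bin edge of an n_bins histogram and
# maximize between-class variance computed directly from the two classes.
oracle_otsu_variance <- function(x, threshold) {
  lo <- x[x <= threshold]; hi <- x[x > threshold]
  if (!length(lo) || !length(hi)) return(0)
  p0 <- length(lo) / length(x); p1 <- 1 - p0
  p0 * p1 * (mean(lo) - mean(hi))^2
}

oracle_otsu_best_variance <- function(x, n_bins = 256L) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  best <- 0
  for (e in edges[2:n_bins])
    best <- max(best, oracle_otsu_variance(x, e))
  best
}

# Distance from a point to an ellipse (center c(y,x), semi-axes (a,b) with a
# along `orientation`), by dense parameter search plus local refinement.
oracle_point_ellipse_distance <- function(p, center, semi_axes, orientation) {
  f <- function(t) {
    ey <- center[1] + semi_axes[1] * cos(t) * sin(orientation) +
      semi_axes[2] * sin(t) * cos(orientation)
    ex <- center[2] + semi_axes[1] * cos(t) * cos(orientation) -
      semi_axes[2] * sin(t) * sin(orientation)
    sqrt((p[1] - ey)^2 + (p[2] - ex)^2)
  }
  tt <- seq(0, 2 * pi, length.out = 720)
  t0 <- tt[which.min(vapply(tt, f, 1))]
  stats::optimize(f, c(t0 - 0.02, t0 + 0.02))$objective
}

# Welch two-sample t-test from the textbook formulas.
oracle_welch_p <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
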