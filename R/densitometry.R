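# Immunoblot densitometry arithmetic for dual-channel infrared blots:
# a precursor band (prelamin A, 800 nm channel) against the summed mature +
# precursor signal (700 nm channel).

#' Normalize blot channels to their per-channel maximum
#'
#' Divides each signal channel by its own maximum across samples so that
#' the brightest sample in each channel reads 1 (the transfection
#' normalization step; it precedes ratio computation).
#'
#' @param measurements data frame with numeric columns
#'   \code{prelamin_signal} and \code{total_signal} (other columns pass
#'   through).
#' @return the data frame with both signal columns rescaled.
#' @export
normalize_channels <- function(measurements) {
  need <- c("prelamin_signal", "total_signal")
  if (!all(need %in% names(measurements)))
    rf_error("measurements need prelamin_signal and total_signal columns",
             "contract_error")
  if (nrow(measurements) == 0) rf_error("no measurements", "contract_error")
  for (col in need) {
    v <- measurements[[col]]
    if (any(v < 0)) rf_error("signals must be non-negative", "contract_error")
    m <- max(v)
    if (m <= 0) rf_error(paste("all-zero channel:", col), "degenerate_error")
    measurements[[col]] <- v / m
  }
  measurements
}

#' Precursor fraction ratio
#'
#' \code{prelamin / (lamin A + prelamin)}: the precursor signal divided by
#' the total (mature + precursor) signal.
#'
#' @param prelamin_signal,total_signal numeric vectors.
#' @return numeric vector of ratios.
#' @export
prelamin_ratio <- function(prelamin_signal, total_signal) {
  if (any(total_signal <= 0))
    rf_error("total_signal must be positive for ratio computation",
             "degenerate_error")
  prelamin_signal / total_signal
}

#' Compare ratio groups with a heteroscedastic t-test
#'
#' Two-tailed Welch (unequal-variance) t-test between two groups of
#' normalized ratios.
#'
#' @param ratios_a,ratios_b numeric vectors, each of length >= 2.
#' @return list with per-group mean and SD, \code{mean_diff} (a - b),
#'   \code{p_value} and the Welch degrees of freedom.
#' @export
compare_groups <- function(ratios_a, ratios_b) {
  if (length(ratios_a) < 2 || length(ratios_b) < 2)
    rf_error("each group needs at least 2 ratios", "contract_error")
  tt <- stats::t.test(ratios_a, ratios_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(mean_a = mean(ratios_a), sd_a = stats::sd(ratios_a),
       mean_b = mean(ratios_b), sd_b = stats::sd(ratios_b),
       mean_diff = mean(ratios_a) - mean(ratios_b),
       p_value = tt$p.value, df = unname(tt$parameter))
}

#' Blot ratio table from raw band signals
#'
#' Convenience wrapper: per-channel max normalization followed by the
#' precursor fraction, returned per sample.
#'
#' @param measurements data frame with columns \code{sample_id},
#'   \code{prelamin_signal}, \code{total_signal} and optionally
#'   \code{group} and \code{replicate_id}.
#' @return the input with normalized signals and a \code{ratio} column.
#' @export
blot_ratios <- function(measurements) {
  norm <- normalize_channels(measurements)
  norm$ratio <- prelamin_ratio(norm$prelamin_signal, norm$total_signal)
  norm
}
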