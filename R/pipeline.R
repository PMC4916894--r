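# Batch orchestration: simulate/load -> project -> segment -> score, with a
# per-nucleus report table and optional QC overlays.

#' Analysis run configuration
#'
#' @param segmentation a \code{\link{segment_config}} list.
#' @param threshold fluctuation-index ratio threshold.
#' @param out_dir optional output directory for the report CSV and QC
#'   overlay PNGs; \code{NULL} keeps everything in memory.
#' @return a config list.
#' @export
run_config <- function(segmentation = segment_config(), threshold = 0.15,
                       out_dir = NULL) {
  list(segmentation = segmentation, threshold = threshold, out_dir = out_dir)
}

analyze_one <- function(stack, config, image_id, label = NA_character_) {
  contours <- segment_nuclei(stack, config$segmentation)
  if (!length(contours)) return(NULL)
  ref_img <- max_intensity_projection(stack, "reference")
  test_img <- max_intensity_projection(stack, "test")
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    fr <- fluctuation_index(sample_contour_intensity(ref_img, ct),
                            sample_contour_intensity(test_img, ct),
                            threshold = config$threshold)
    data.frame(image_id = image_id, nucleus_id = i, group = label,
               n_points = fr$n_points, fraction_12 = fr$fraction_12,
               fraction_21 = fr$fraction_21, index = fr$index,
               threshold = fr$threshold, qc = "ok",
               stringsAsFactors = FALSE)
  })
  list(rows = do.call(rbind, rows), contours = contours)
}

#' Run the full analysis over a batch of images
#'
#' Each input is segmented (Otsu + GVF snake), reference and test profiles
#' are sampled on every refined contour, and the fluctuation index is
#' computed per nucleus. Failures are isolated per image: a failing image
#' is logged and skipped, and only an all-failed batch is an error.
#'
#' @param inputs either a list of entries \code{list(stack, label, id)}
#'   (e.g. from \code{\link{generate_cohort}}, or \code{list(stack =
#'   generate_nucleus_image(spec)$stack)}), or a character vector of TIFF
#'   paths read with \code{role_map}.
#' @param config a \code{\link{run_config}}.
#' @param role_map role map used when \code{inputs} are file paths.
#' @return data frame of per-nucleus rows (image_id, nucleus_id, group,
#'   n_points, fraction_12, fraction_21, index, threshold, qc); written to
#'   \code{out_dir/report.csv} when an output directory is configured,
#'   along with one contour-overlay PNG per image.
#' @export
run_analysis <- function(inputs, config = run_config(),
                         role_map = c(counterstain = 1, reference = 2, test = 3)) {
  if (is.character(inputs))
    inputs <- lapply(inputs, function(p)
      list(stack = read_stack(p, role_map), label = NA_character_,
           id = sub("\\.[^.]*$", "", basename(p))))
  all_rows <- list(); n_fail <- 0L
  for (i in seq_along(inputs)) {
    entry <- inputs[[i]]
    id <- if (!is.null(entry$id)) entry$id else sprintf("image_%03d", i)
    label <- if (!is.null(entry$label)) entry$label else NA_character_
    res <- tryCatch(analyze_one(entry$stack, config, id, label),
                    error = function(e) {
                      message(sprintf("image %s failed: %s", id, conditionMessage(e)))
                      n_fail <<- n_fail + 1L
                      NULL
                    })
    if (is.null(res)) next
    all_rows[[length(all_rows) + 1L]] <- res$rows
    if (!is.null(config$out_dir))
      write_overlay(entry$stack, res$contours,
                    file.path(config$out_dir, paste0(id, "_overlay.png")))
  }
  if (n_fail == length(inputs) && length(inputs) > 0)
    rf_error("all images failed", "batch_error")
  report <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(image_id = character(), nucleus_id = integer(),
               group = character(), n_points = integer(),
               fraction_12 = numeric(), fraction_21 = numeric(),
               index = numeric(), threshold = numeric(), qc = character())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  }
  report
}

# QC overlay: grayscale composite with the contour burned in.
write_overlay <- function(stack, contours, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  img <- as_matrix(max_intensity_projection(stack, "reference"))
  rng <- range(img)
  g <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  rgb <- array(g, c(dim(g), 3))
  for (ct in contours) {
    iy <- pmin(pmax(round(ct[, 1]), 1), nrow(g))
    ix <- pmin(pmax(round(ct[, 2]), 1), ncol(g))
    rgb[cbind(iy, ix, 1)] <- 1
    rgb[cbind(iy, ix, 2)] <- 0.2
    rgb[cbind(iy, ix, 3)] <- 0.2
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Summarize fluctuation indices by group
#'
#' Per-group descriptive statistics of the per-nucleus index, with a
#' Mann-Whitney (Wilcoxon rank-sum) comparison when exactly two groups with
#' at least 3 nuclei each are present.
#'
#' @param report data frame from \code{\link{run_analysis}}.
#' @param alternative passed to \code{wilcox.test}; the default
#'   \code{"two.sided"} is a reporting convenience, use \code{"greater"}
#'   for a directional punctate-vs-uniform question (first group level vs
#'   second).
#' @return list with \code{summary} (per-group n, mean, sd, median, IQR)
#'   and \code{test} (list with p_value and W, or NULL with a warning when
#'   fewer than two adequate groups exist).
#' @export
summarize_groups <- function(report, alternative = "two.sided") {
  groups <- split(report$index, report$group)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), iqr = stats::IQR(v),
               stringsAsFactors = FALSE)
  }))
  ok <- names(groups)[vapply(groups, length, 1L) >= 3]
  test <- NULL
  if (length(ok) == 2) {
    wt <- stats::wilcox.test(groups[[ok[1]]], groups[[ok[2]]],
                             alternative = alternative, exact = FALSE)
    test <- list(groups = ok, p_value = wt$p.value, W = unname(wt$statistic))
  } else {
    warning("need exactly 2 groups with >= 3 nuclei for a rank-sum test")
  }
  list(summary = summ, test = test)
}
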