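#' Multi-channel image stack
#'
#' Container for a multi-channel, optionally multi-slice fluorescence image.
#' Pixel data are held as a 4D numeric array indexed \code{[y, x, z, channel]}
#' (z = 1 for 2D fields); all arithmetic downstream is done in double
#' precision regardless of the on-disk pixel type.
#'
#' @param channels list of numeric matrices (2D, one per channel) or a 4D
#'   array \code{[y, x, z, channel]}. All channels must share dimensions.
#' @param roles named integer vector mapping role names
#'   (\code{"counterstain"}, \code{"reference"}, \code{"test"}, or other
#'   labels) to channel indices.
#' @param pixel_size optional pixel size in micrometers.
#' @param z_step optional z spacing in micrometers.
#' @return an \code{image_stack} object.
#' @export
image_stack <- function(channels, roles, pixel_size = NULL, z_step = NULL) {
  if (is.list(channels)) {
    dims <- lapply(channels, dim)
    if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
      rf_error("all channels must share (y, x) dimensions", "shape_error")
    arr <- array(0, c(dim(channels[[1]])[1:2],
                      if (length(dim(channels[[1]])) == 3) dim(channels[[1]])[3] else 1L,
                      length(channels)))
    for (i in seq_along(channels)) {
      ch <- channels[[i]]
      if (length(dim(ch)) == 2) dim(ch) <- c(dim(ch), 1L)
      arr[, , , i] <- ch
    }
  } else {
    arr <- channels
    if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 4)
      rf_error("channel data must be a list of matrices or a 4D array", "shape_error")
  }
  storage.mode(arr) <- "double"
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    rf_error("roles must be a named vector of channel indices", "role_error")
  if (any(roles < 1 | roles > dim(arr)[4]))
    rf_error("role map references channels outside the stack", "role_error")
  structure(list(data = arr, roles = roles,
                 pixel_size = pixel_size, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d z-slice(s), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat("  roles:", paste(sprintf("%s=%d", names(x$roles), x$roles),
                        collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(stack) dim(stack$data)[4]
n_slices   <- function(stack) dim(stack$data)[3]

# Resolve a channel given as role name or index; errors on missing roles.
resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    if (!channel %in% names(stack$roles))
      rf_error(sprintf("stack has no channel with role '%s'", channel), "role_error")
    ch <- stack$roles[[channel]]
  } else ch <- as.integer(channel)
  if (ch < 1 || ch > n_channels(stack))
    rf_error("channel index out of range", "role_error")
  ch
}

require_roles <- function(stack, roles) {
  missing <- setdiff(roles, names(stack$roles))
  if (length(missing))
    rf_error(paste("stack is missing required channel role(s):",
                   paste(missing, collapse = ", ")), "role_error")
  invisible(stack)
}

image2d <- function(mat, provenance, channel = NA) {
  structure(mat, class = c("image2d", class(matrix())),
            provenance = provenance, channel = channel)
}

as_matrix <- function(img) {
  attributes(img) <- list(dim = dim(img))
  img
}

#' Read a multi-page TIFF into an image stack
#'
#' Accepts 8/16-bit integer and float pixel data; intensities are promoted
#' to double precision (integer data keep their raw count values).
#'
#' @param path TIFF file path.
#' @param role_map named vector mapping roles to channel indices, e.g.
#'   \code{c(counterstain = 1, reference = 2, test = 3)}.
#' @param layout how pages are organised: \code{"channels"} (each page is one
#'   channel, z = 1) or \code{"z"} (each page is one slice of a single- or
#'   multi-channel stack; with \code{n_channels > 1} pages cycle through
#'   channels fastest).
#' @param n_channels number of channels when \code{layout = "z"}.
#' @param pixel_size,z_step optional calibration, micrometers.
#' @return an \code{image_stack}.
#' @export
read_stack <- function(path, role_map, layout = c("channels", "z"),
                       n_channels = NULL, pixel_size = NULL, z_step = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) rf_error(paste("cannot read", path), "io_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale-as-RGB pages
    storage.mode(p) <- "double"
    p
  })
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    rf_error("TIFF pages have inconsistent shapes", "shape_error")
  if (layout == "channels") {
    stack <- image_stack(pages, roles = role_map,
                         pixel_size = pixel_size, z_step = z_step)
  } else {
    nc <- if (is.null(n_channels)) 1L else as.integer(n_channels)
    if (length(pages) %% nc != 0)
      rf_error("page count is not a multiple of n_channels", "shape_error")
    nz <- length(pages) %/% nc
    arr <- array(0, c(dim(pages[[1]]), nz, nc))
    k <- 1L
    for (z in seq_len(nz)) for (ch in seq_len(nc)) {
      arr[, , z, ch] <- pages[[k]]; k <- k + 1L
    }
    stack <- image_stack(arr, roles = role_map,
                         pixel_size = pixel_size, z_step = z_step)
  }
  stack
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are written channel by channel (z fastest within channel) as
#' unsigned integer TIFF; intensities are rounded to integer counts and
#' clamped to the bit-depth range, mirroring a camera export.
#'
#' @param stack an \code{image_stack}.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) rf_error("bits must be 8 or 16", "io_error")
  maxval <- 2^bits - 1
  pages <- list()
  for (ch in seq_len(n_channels(stack)))
    for (z in seq_len(n_slices(stack))) {
      q <- pmin(pmax(round(stack$data[, , z, ch]), 0), maxval)
      pages[[length(pages) + 1L]] <- q / maxval
    }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over z, the 2D reduction used for quantification.
#'
#' @param stack an \code{image_stack}.
#' @param channel role name or channel index.
#' @return an \code{image2d} matrix with provenance \code{"MIP"}.
#' @export
max_intensity_projection <- function(stack, channel) {
  ch <- resolve_channel(stack, channel)
  arr <- stack$data[, , , ch, drop = FALSE]
  out <- apply(arr, c(1, 2), max)
  image2d(out, provenance = "MIP", channel = channel)
}

#' Average projection over a z window
#'
#' Per-pixel mean over selected slices, as used for display projections
#' (e.g. a 1 um window at 0.2 um z-steps averages 5 slices).
#'
#' @param stack an \code{image_stack}.
#' @param channel role name or channel index.
#' @param z_range integer vector of slice indices; if \code{NULL}, derived
#'   from \code{window_um} and the stack's \code{z_step}, centered on
#'   \code{center_slice}.
#' @param window_um physical window size in micrometers.
#' @param center_slice slice at the window center (default: middle slice).
#' @return an \code{image2d} with provenance \code{"average"}.
#' @export
average_projection <- function(stack, channel, z_range = NULL,
                               window_um = NULL, center_slice = NULL) {
  ch <- resolve_channel(stack, channel)
  nz <- n_slices(stack)
  if (is.null(z_range)) {
    if (is.null(window_um) || is.null(stack$z_step))
      z_range <- seq_len(nz)
    else {
      nw <- max(1L, round(window_um / stack$z_step))
      c0 <- if (is.null(center_slice)) ceiling(nz / 2) else center_slice
      half <- (nw - 1L) %/% 2L
      z_range <- (c0 - half):(c0 - half + nw - 1L)
    }
  }
  z_range <- as.integer(z_range)
  if (length(z_range) == 0) rf_error("empty z_range", "range_error")
  if (any(z_range < 1 | z_range > nz))
    rf_error("z_range outside the stack", "range_error")
  arr <- stack$data[, , z_range, ch, drop = FALSE]
  out <- apply(arr, c(1, 2), mean)
  image2d(out, provenance = "average", channel = channel)
}
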