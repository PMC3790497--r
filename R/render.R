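#' Render a 2-D super-resolution image from localizations
#'
#' Bins localizations on a regular grid covering the data bounding box and,
#' optionally, convolves the count histogram with a normalized Gaussian
#' kernel (the usual Gaussian-rendered STORM image). With `blur_sd = 0` the
#' grid is a plain 2-D histogram whose total equals the number of rendered
#' localizations; with `blur_sd > 0` total mass is conserved to within
#' floating-point error whenever the kernel support lies inside the grid,
#' because the discrete kernel is normalized to unit sum.
#'
#' @param table a [localization_table()].
#' @param bin_size grid bin size in nm (> 0).
#' @param blur_sd Gaussian rendering kernel SD in nm (>= 0).
#' @param channel optional channel label; `NULL` renders each channel.
#' @param pad extra margin in nm added around the bounding box (defaults to
#'   `4 * blur_sd` so the kernel support of interior points stays in-grid).
#' @return object of class `storm_image`: list with per-channel matrices
#'   (`images`, row-major, row 1 = minimum y), common `x_edges`/`y_edges`,
#'   and `empty` flag. Empty selections yield a flagged empty grid, not an
#'   error.
#' @export
render_image <- function(table, bin_size, blur_sd = 0, channel = NULL,
                         pad = NULL) {
  stopifnot(bin_size > 0, blur_sd >= 0)
  validate_localization_table(table)
  channels <- if (is.null(channel)) attr(table, "channels") else channel
  sel <- table[table$channel %in% channels, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(structure(list(images = list(), x_edges = numeric(0),
                          y_edges = numeric(0), bin_size = bin_size,
                          blur_sd = blur_sd, empty = TRUE),
                     class = "storm_image"))
  }
  # margin wide enough that the truncated kernel support of every point
  # (anywhere within its bin) stays inside the grid
  if (is.null(pad)) {
    pad <- if (blur_sd > 0) {
      (ceiling(4 * blur_sd / bin_size) + 1) * bin_size
    } else 0
  }
  x_edges <- grid_edges(range(sel$x), bin_size, pad)
  y_edges <- grid_edges(range(sel$y), bin_size, pad)
  images <- lapply(channels, function(ch) {
    pts <- sel[sel$channel == ch, , drop = FALSE]
    img <- bin2d(pts$x, pts$y, x_edges, y_edges)
    if (blur_sd > 0 && nrow(pts) > 0L) {
      img <- gaussian_blur(img, blur_sd / bin_size)
    }
    img
  })
  names(images) <- channels
  structure(list(images = images, x_edges = x_edges, y_edges = y_edges,
                 bin_size = bin_size, blur_sd = blur_sd, empty = FALSE),
            class = "storm_image")
}

grid_edges <- function(rng, bin_size, pad) {
  lo <- rng[1L] - pad
  hi <- rng[2L] + pad
  n <- max(1L, ceiling((hi - lo) / bin_size - 1e-9))
  seq(lo, by = bin_size, length.out = n + 1L)
}

# 2-D count histogram; rows index y, columns index x, half-open upper bins
# except the last, so every point in the box is counted exactly once.
bin2d <- function(x, y, x_edges, y_edges) {
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ix <- pmin(nx, pmax(1L, findInterval(x, x_edges,
                                       rightmost.closed = TRUE)))
  iy <- pmin(ny, pmax(1L, findInterval(y, y_edges,
                                       rightmost.closed = TRUE)))
  counts <- tabulate(iy + ny * (ix - 1L), nbins = nx * ny)
  matrix(counts, nrow = ny, ncol = nx)
}

# Separable Gaussian convolution with a unit-sum discrete kernel (truncated
# at 4 sd); zero padding at the boundary.
gaussian_blur <- function(img, sd_bins) {
  if (sd_bins <= 0) return(img)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  img <- apply_kernel_rows(img, k)
  t(apply_kernel_rows(t(img), k))
}

apply_kernel_rows <- function(img, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  padded <- rbind(matrix(0, half, ncol(img)), img,
                  matrix(0, half, ncol(img)))
  out <- matrix(0, n, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Write a rendered image to TIFF (and optional PNG preview)
#'
#' The TIFF stores the float intensity grid (one file per channel when the
#' render holds several); the PNG preview is gamma-free min-max scaled.
#' Pixel (row 1, column 1) is the minimum-x / minimum-y corner.
#'
#' @param image a `storm_image` from [render_image()].
#' @param path output TIFF path; channel names are suffixed when the render
#'   holds more than one channel.
#' @param png_preview optional PNG path (single channel or first channel).
#' @return character vector of files written, invisibly.
#' @export
write_rendered_image <- function(image, path, png_preview = NULL) {
  stopifnot(inherits(image, "storm_image"))
  if (image$empty) stop("cannot write an empty render", call. = FALSE)
  written <- character(0)
  multi <- length(image$images) > 1L
  for (ch in names(image$images)) {
    p <- if (multi) {
      sub("(\\.tiff?)?$", paste0("_", gsub("[^A-Za-z0-9]+", "_", ch),
                                 ".tif"), path)
    } else {
      path
    }
    m <- image$images[[ch]]
    scaled <- if (max(m) > 0) m / max(m) else m
    tiff::writeTIFF(scaled, p, bits.per.sample = 32L)
    written <- c(written, p)
  }
  if (!is.null(png_preview)) {
    m <- image$images[[1L]]
    scaled <- if (max(m) > 0) m / max(m) else m
    png::writePNG(scaled, png_preview)
    written <- c(written, png_preview)
  }
  invisible(written)
}
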