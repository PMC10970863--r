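#' Pad a mask to a dyadic square canvas
#'
#' Embeds the mask in the top-left corner of a square canvas whose side is
#' the next power of two at or above `max(H, W)`, padding with background.
#' Box sizes then halve cleanly from the full canvas down to one pixel, and
#' the foreground pixel count is unchanged.
#'
#' @param bimg a [binary_image].
#' @return A [binary_image] on a dyadic square canvas.
#' @export
pad_to_dyadic <- function(bimg) {
  stopifnot(inherits(bimg, "binary_image"))
  m <- bimg$mask
  side <- 2^ceiling(log2(max(dim(m))))
  if (side == nrow(m) && side == ncol(m)) return(bimg)
  out <- matrix(FALSE, side, side)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  binary_image(out, threshold = bimg$threshold)
}

#' Dyadic box counting of a binary mask
#'
#' Counts, for every dyadic box size r in 1, 2, 4, ..., up to the padded
#' canvas side, the number of aligned r x r grid boxes containing at least
#' one foreground pixel. The grid is anchored at the top-left corner; the
#' mask is padded to a dyadic square first (see [pad_to_dyadic()]), so counts
#' satisfy n(2r) <= n(r) <= 4 n(2r), n(1) equals the number of foreground
#' pixels, and n at the largest scale is 1 for any non-empty mask.
#'
#' Internally the occupancy grid is OR-reduced over 2 x 2 blocks at each
#' scale, which is exactly equivalent to scanning all aligned tiles.
#'
#' @param bimg a [binary_image].
#' @return An object of class `box_count_curve` with elements `r` (box
#'   sizes), `n` (occupied-box counts) and `padded_side`.
#' @export
box_count <- function(bimg) {
  p <- pad_to_dyadic(bimg)
  m <- p$mask
  side <- nrow(m)
  k_max <- as.integer(round(log2(side)))
  r <- 2^(0:k_max)
  n <- integer(k_max + 1L)
  n[1] <- sum(m)
  cur <- m
  for (k in seq_len(k_max)) {
    s <- nrow(cur)
    cur <- cur[seq(1L, s, by = 2L), , drop = FALSE] |
      cur[seq(2L, s, by = 2L), , drop = FALSE]
    cur <- cur[, seq(1L, s, by = 2L), drop = FALSE] |
      cur[, seq(2L, s, by = 2L), drop = FALSE]
    n[k + 1L] <- sum(cur)
  }
  structure(list(r = r, n = n, padded_side = side),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("<box_count_curve> side %d px, %d scales, n(1) = %d\n",
              x$padded_side, length(x$r), x$n[1]))
  invisible(x)
}

#' Global box-counting fractal dimension
#'
#' Ordinary least-squares slope magnitude of log n(r) against log(1/r) over
#' the scales with non-zero counts. With fewer than two such scales the
#' estimate is degenerate and 0 is returned, flagged in attribute
#' `"degenerate"`.
#'
#' @param curve a `box_count_curve`.
#' @return The fractal dimension (a single number); attribute `"degenerate"`
#'   is `TRUE` when the regression could not be formed.
#' @export
global_fd <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  ok <- curve$n > 0
  if (sum(ok) < 2L) return(structure(0, degenerate = TRUE))
  x <- log(1 / curve$r[ok])
  y <- log(curve$n[ok])
  slope <- stats::cov(x, y) / stats::var(x)
  structure(abs(slope), degenerate = FALSE)
}

#' Local (per-scale) fractal dimension
#'
#' The negative discrete gradient of log2 n(r) with respect to log2 r,
#' central differences at interior scales and one-sided differences at the
#' two ends. Scales with zero counts (empty mask) are marked invalid and the
#' gradient is not interpolated across them.
#'
#' @param curve a `box_count_curve`.
#' @return An object of class `local_fd_curve` with elements `r`, `d`
#'   (local dimension, `NA` where invalid) and `valid`.
#' @export
local_fd <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  nr <- length(curve$r)
  valid <- curve$n > 0
  d <- rep(NA_real_, nr)
  if (any(valid)) {
    # occupancy is hereditary across scales: if any pixel is set, n(r) >= 1
    # at every r, so the valid set is all scales or none
    ln <- log2(curve$n)
    lr <- log2(curve$r)
    if (nr >= 2L) {
      d[1] <- -(ln[2] - ln[1]) / (lr[2] - lr[1])
      d[nr] <- -(ln[nr] - ln[nr - 1]) / (lr[nr] - lr[nr - 1])
      if (nr > 2L) {
        i <- 2:(nr - 1L)
        d[i] <- -(ln[i + 1L] - ln[i - 1L]) / (lr[i + 1L] - lr[i - 1L])
      }
    } else {
      d[1] <- 0
    }
  }
  structure(list(r = curve$r, d = d, valid = valid),
            class = "local_fd_curve")
}

#' Summarize a fractal-dimension estimate over scales
#'
#' Mean and standard deviation (sample, n-1) of the local fractal dimension
#' over valid scales, optionally restricted to a box-size band, together
#' with the global regression slope. An empty mask (or empty band) yields a
#' degenerate summary with mean 0.
#'
#' @param x a `box_count_curve` or a `local_fd_curve`.
#' @param scale_range optional `c(r_min, r_max)` in pixels restricting the
#'   scales summarized (inclusive).
#' @param curve when `x` is a `local_fd_curve`, the originating
#'   `box_count_curve` (needed for the global slope); otherwise ignored.
#' @return An object of class `fd_summary`: `global_fd`, `mean_fd`,
#'   `std_fd`, `n_scales`, `degenerate`.
#' @export
fd_summary <- function(x, scale_range = NULL, curve = NULL) {
  if (inherits(x, "box_count_curve")) {
    curve <- x
    local <- local_fd(curve)
  } else if (inherits(x, "local_fd_curve")) {
    local <- x
  } else {
    stop("`x` must be a box_count_curve or local_fd_curve")
  }
  gfd <- if (is.null(curve)) NA_real_ else as.numeric(global_fd(curve))
  keep <- local$valid & !is.na(local$d)
  if (!is.null(scale_range)) {
    keep <- keep & local$r >= scale_range[1] & local$r <= scale_range[2]
  }
  if (!any(keep)) {
    return(structure(list(global_fd = 0, mean_fd = 0, std_fd = 0,
                          n_scales = 0L, degenerate = TRUE),
                     class = "fd_summary"))
  }
  d <- local$d[keep]
  structure(list(global_fd = gfd,
                 mean_fd = mean(d),
                 std_fd = if (length(d) > 1L) stats::sd(d) else 0,
                 n_scales = length(d),
                 degenerate = FALSE),
            class = "fd_summary")
}

#' @export
print.fd_summary <- function(x, ...) {
  cat(sprintf("<fd_summary> mean FD %.3f (sd %.3f) over %d scales, global FD %.3f%s\n",
              x$mean_fd, x$std_fd, x$n_scales, x$global_fd,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fractal dimension as a function of the binarization threshold
#'
#' The per-image signature: for every threshold of the sweep (default 0,
#' 5, ..., 255), the image is binarized, box counted, and summarized by the
#' mean local fractal dimension over scales. Thresholds whose mask is empty
#' are recorded as 0 with `degenerate = TRUE`.
#'
#' @param img a [gray_image].
#' @param start,stop,step threshold sweep, as in [threshold_sweep()].
#' @param scale_range optional box-size band (pixels) passed to
#'   [fd_summary()].
#' @return An object of class `fd_threshold_curve`, a data frame with
#'   columns `threshold`, `mean_fd`, `std_fd`, `global_fd`, `degenerate`.
#' @export
fd_threshold_curve <- function(img, start = 0, stop = 255, step = 5,
                               scale_range = NULL) {
  stopifnot(inherits(img, "gray_image"))
  ts <- seq(start, stop, by = step)
  rows <- lapply(ts, function(T) {
    s <- fd_summary(box_count(binarize(img, T)), scale_range = scale_range)
    data.frame(threshold = T, mean_fd = s$mean_fd, std_fd = s$std_fd,
               global_fd = s$global_fd, degenerate = s$degenerate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fd_threshold_curve", "data.frame")
  out
}

#' Tabulate a box-count curve with its local dimension
#'
#' @param curve a `box_count_curve`.
#' @return A data frame with columns `r`, `n`, `local_fd`.
#' @export
as_fd_table <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  l <- local_fd(curve)
  data.frame(r = curve$r, n = curve$n, local_fd = l$d)
}
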