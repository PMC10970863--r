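#' Gray-level co-occurrence matrix at a fixed offset
#'
#' Counts ordered pixel pairs: cell (i, j) is the number of positions (p, q)
#' with intensity i at (p, q) and intensity j at (p + dr, q + dc), where the
#' offset is given as (row shift, column shift). Pairs falling outside the
#' image are skipped. The matrix is asymmetric (no transposed pairs are
#' added). Counts are normalized by the total pair count R to give the joint
#' probability table p(i, j).
#'
#' @param img a [gray_image].
#' @param offset integer vector `c(drow, dcol)`; e.g. `c(0, 1)` pairs each
#'   pixel with the pixel immediately to its right.
#' @param Ng number of gray levels (default 256, the full 8-bit range).
#'   When `Ng < 256` the image is re-quantized by uniform binning of
#'   [0, 255] into `Ng` levels, unless the image already uses levels
#'   `0 .. Ng-1` only, which are taken as-is.
#' @return An object of class `glcm`: `counts` (Ng x Ng integer), `p`
#'   (normalized), `R` (total pairs), `Ng`, `offset`.
#' @export
glcm <- function(img, offset, Ng = 256) {
  stopifnot(inherits(img, "gray_image"))
  if (length(offset) != 2L || any(offset != round(offset))) {
    stop("`offset` must be two integers c(drow, dcol)")
  }
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  px <- img$pixels
  if (Ng < 256 && max(px) >= Ng) {
    # uniform re-quantization of the 8-bit range
    px <- matrix(as.integer(floor(px / 256 * Ng)), nrow(px), ncol(px))
  }
  H <- nrow(px); W <- ncol(px)
  rows <- seq_len(H); cols <- seq_len(W)
  rows <- rows[rows + dr >= 1L & rows + dr <= H]
  cols <- cols[cols + dc >= 1L & cols + dc <= W]
  if (length(rows) == 0L || length(cols) == 0L) {
    stop(sprintf("offset (%d, %d) admits no pixel pairs on a %d x %d image",
                 dr, dc, H, W))
  }
  i <- px[rows, cols, drop = FALSE]
  j <- px[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.vector(i) * Ng + as.vector(j) + 1L, nbins = Ng * Ng)
  counts <- matrix(counts, Ng, Ng, byrow = TRUE)  # row = i, col = j
  R <- length(rows) * length(cols)
  structure(list(counts = counts, p = counts / R, R = R, Ng = Ng,
                 offset = c(dr, dc)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> Ng = %d, offset (%d, %d), R = %d pairs\n",
              x$Ng, x$offset[1], x$offset[2], x$R))
  invisible(x)
}

#' Marginal statistics of a normalized co-occurrence matrix
#'
#' Row and column marginals px(i), py(j) with their means and population
#' standard deviations, as used by the correlation descriptor.
#'
#' @param g a [glcm].
#' @return List with `px`, `py`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`.
#'   Gray levels are indexed 0 .. Ng-1.
#' @export
marginal_stats <- function(g) {
  stopifnot(inherits(g, "glcm"))
  lev <- 0:(g$Ng - 1L)
  px <- rowSums(g$p)
  py <- colSums(g$p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
       sigma_x = sqrt(sum((lev - mu_x)^2 * px)),
       sigma_y = sqrt(sum((lev - mu_y)^2 * py)))
}

#' Haralick descriptors of one co-occurrence matrix
#'
#' Four classical texture descriptors of the normalized GLCM p(i, j):
#' \describe{
#'   \item{ASM}{angular second moment (energy), `sum p^2`; 1 for a
#'     perfectly ordered (single-cell) distribution.}
#'   \item{CON}{contrast, `sum (i-j)^2 p(i,j)`, weighting co-occurrences by
#'     the squared gray-level difference.}
#'   \item{COR}{correlation of the paired gray levels,
#'     `(sum i j p(i,j) - mu_x mu_y) / (sigma_x sigma_y)` with population
#'     marginal standard deviations; if either marginal is degenerate
#'     (sigma = 0) the correlation is set to 1.}
#'   \item{ENT}{entropy, `-sum p log p` with 0 log 0 = 0; natural log by
#'     default.}
#' }
#'
#' @param g a [glcm].
#' @param entropy_base base of the entropy logarithm (default `exp(1)`).
#' @return Named numeric vector `c(ASM, CON, COR, ENT)`.
#' @export
haralick <- function(g, entropy_base = exp(1)) {
  stopifnot(inherits(g, "glcm"))
  if (abs(sum(g$p) - 1) > 1e-9) {
    stop("GLCM probabilities are not normalized")
  }
  p <- g$p
  lev <- 0:(g$Ng - 1L)
  asm <- sum(p^2)
  dif2 <- outer(lev, lev, function(i, j) (i - j)^2)
  con <- sum(dif2 * p)
  m <- marginal_stats(g)
  cor_val <- if (m$sigma_x == 0 || m$sigma_y == 0) {
    1
  } else {
    (sum(outer(lev, lev) * p) - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  }
  nz <- p[p > 0]
  ent <- -sum(nz * log(nz, base = entropy_base))
  c(ASM = asm, CON = con, COR = cor_val, ENT = ent)
}

# standard four-direction offsets (row, col) at pixel distance D
.direction_offsets <- function(D = 1L) {
  list(deg0   = c(0L, D),
       deg45  = c(-D, D),
       deg90  = c(-D, 0L),
       deg135 = c(-D, -D))
}

#' Haralick descriptors in the four standard directions
#'
#' Computes the co-occurrence matrix at pixel distance `D` for the offsets
#' 0 deg (0, D), 45 deg (-D, D), 90 deg (-D, 0) and 135 deg (-D, -D), the
#' four descriptors for each, and their arithmetic mean across directions
#' (`mu`).
#'
#' @param img a [gray_image] large enough to admit all four offsets.
#' @param D pixel distance of the offset (default 1, horizontally adjacent).
#' @param Ng number of gray levels (default 256).
#' @param entropy_base base of the entropy logarithm.
#' @return An object of class `haralick_features`, a data frame with
#'   columns `feature`, `deg0`, `deg45`, `deg90`, `deg135`, `mu`.
#' @export
haralick_all_directions <- function(img, D = 1, Ng = 256,
                                    entropy_base = exp(1)) {
  offs <- .direction_offsets(as.integer(D))
  vals <- lapply(names(offs), function(dir) {
    g <- tryCatch(glcm(img, offs[[dir]], Ng = Ng),
                  error = function(e) stop("direction ", dir, ": ",
                                           conditionMessage(e)))
    haralick(g, entropy_base = entropy_base)
  })
  names(vals) <- names(offs)
  m <- do.call(cbind, vals)      # 4 features x 4 directions
  out <- data.frame(feature = rownames(m), m, mu = rowMeans(m),
                    row.names = NULL)
  class(out) <- c("haralick_features", "data.frame")
  out
}

#' Average Haralick feature tables
#'
#' Unweighted arithmetic mean, per direction and of the directional mean
#' `mu`, across a list of feature tables: image-level tables average to a
#' sample-level summary, sample-level summaries to a condition-level one.
#'
#' @param features non-empty list of `haralick_features` (or previously
#'   aggregated `texture_summary`) tables.
#' @param level one of `"sample"` or `"condition"` (a label recording the
#'   aggregation level; the arithmetic is identical).
#' @return An object of class `texture_summary` (and
#'   `haralick_features`/data frame), with attributes `level` and `n_items`.
#' @export
aggregate_haralick <- function(features, level = c("sample", "condition")) {
  level <- match.arg(level)
  if (!is.list(features) || length(features) == 0L ||
      inherits(features, "data.frame")) {
    stop("`features` must be a non-empty list of feature tables")
  }
  ref <- features[[1]]
  num_cols <- c("deg0", "deg45", "deg90", "deg135", "mu")
  acc <- Reduce(`+`, lapply(features, function(f) {
    stopifnot(identical(f$feature, ref$feature))
    as.matrix(f[, num_cols])
  }))
  out <- data.frame(feature = ref$feature, acc / length(features),
                    row.names = NULL)
  class(out) <- c("texture_summary", "haralick_features", "data.frame")
  attr(out, "level") <- level
  attr(out, "n_items") <- length(features)
  out
}

#' Round a feature table for report export
#'
#' Applies 3-decimal half-up rounding, the convention used for printed
#' descriptor tables; internal values keep full precision.
#'
#' @param features a `haralick_features` data frame.
#' @param digits decimal places (default 3).
#' @return A plain data frame with rounded numeric columns.
#' @export
format_haralick <- function(features, digits = 3) {
  num <- vapply(features, is.numeric, logical(1))
  features[num] <- lapply(features[num], round_half_up, digits = digits)
  as.data.frame(features)
}

#' Bundled reference Haralick descriptor table
#'
#' Per-sample four-direction Haralick descriptors (ASM, CON, COR, ENT, plus
#' the directional mean `mu`) for six transmitted-light powder samples,
#' three in-specification and three out-of-specification, at 3-decimal
#' precision. Useful for exercising the aggregation conventions
#' (direction mean, condition mean) against independently tabulated values.
#'
#' @return Data frame with columns `sample_id`, `condition`, `feature`,
#'   `deg0`, `deg45`, `deg90`, `deg135`, `mu`.
#' @export
reference_haralick_table <- function() {
  utils::read.csv(system.file("extdata", "reference_haralick_by_sample.csv",
                              package = "powdertex", mustWork = TRUE))
}
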