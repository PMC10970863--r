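#' Autoscale a data matrix
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (n-1 denominator), the standard chemometric pre-processing
#' before PCA. Zero-variance columns carry no information on this scale and
#' are dropped with a warning; their names are recorded.
#'
#' @param X numeric matrix or data frame, samples in rows, variables in
#'   columns. At least two rows are required.
#' @return List of class `autoscale`: `X` (scaled matrix), `center`,
#'   `scale` (per retained variable), `dropped` (names or indices of
#'   zero-variance columns).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 samples")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  keep <- sdev > 0
  if (!any(keep)) stop("all columns have zero variance; nothing to scale")
  dropped <- colnames(X)[!keep]
  if (is.null(dropped)) dropped <- which(!keep)
  if (any(!keep)) {
    warning(sprintf("dropped %d zero-variance column(s)", sum(!keep)))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  structure(list(X = Xs, center = mu[keep], scale = sdev[keep],
                 dropped = dropped),
            class = "autoscale")
}

#' Principal component analysis of an autoscaled matrix
#'
#' Singular value decomposition of the column-centered (here: autoscaled)
#' matrix. Loadings are the right singular vectors (orthonormal columns),
#' scores the projections of the rows onto them, and the explained variance
#' per component is the squared singular value as a percentage of the total.
#' Loading signs follow a deterministic convention: the largest-magnitude
#' element of each loading vector is positive.
#'
#' @param X autoscaled matrix (samples x variables), or an [autoscale]
#'   result.
#' @param n_components number of components to retain; defaults to the full
#'   rank bound `min(n_samples - 1, n_variables)`.
#' @return An object of class `pca_model`: `loadings` (variables x
#'   components), `scores` (samples x components), `explained_variance_pct`,
#'   `singular_values`, `n_samples`.
#' @export
fit_pca <- function(X, n_components = NULL) {
  if (inherits(X, "autoscale")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || p < 2L) stop("PCA needs at least 2 samples and 2 variables")
  k_max <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) {
    stop(sprintf("n_components = %d exceeds min(samples - 1, variables) = %d",
                 n_components, k_max))
  }
  s <- svd(X, nu = 0, nv = k_max)
  d <- s$d[seq_len(k_max)]
  V <- s$v
  # deterministic orientation: largest-|loading| element positive
  for (k in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, k]))
    if (V[piv, k] < 0) V[, k] <- -V[, k]
  }
  ev_pct <- d^2 / sum(s$d^2) * 100
  keep <- seq_len(n_components)
  scores <- X %*% V[, keep, drop = FALSE]
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  colnames(scores) <- paste0("PC", keep)
  rownames(scores) <- rownames(X)
  structure(list(loadings = V[, keep, drop = FALSE],
                 scores = scores,
                 explained_variance_pct = ev_pct[keep],
                 singular_values = d[keep],
                 n_samples = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d samples, %d variables, %d components\n",
              x$n_samples, nrow(x$loadings), ncol(x$loadings)))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Per-group 95% confidence ellipses on a scores plane
#'
#' For each group, the centroid and covariance of its (PC1, PC2) scores;
#' the ellipse boundary is the set of points at squared Mahalanobis distance
#' equal to the chi-square quantile with 2 degrees of freedom at the chosen
#' confidence level. Groups with fewer than 3 points are skipped with a
#' warning; singular (collinear) covariances are flagged.
#'
#' @param scores numeric matrix with at least 2 columns (PC1, PC2 used).
#' @param labels group label per row.
#' @param level confidence level (default 0.95).
#' @return Named list of `group_ellipse` objects: `group`, `center`,
#'   `covariance`, `level`, `radius2` (chi-square quantile), `singular`.
#' @export
ellipse95 <- function(scores, labels, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) >= 2L, nrow(scores) == length(labels))
  out <- list()
  for (g in unique(labels)) {
    pts <- scores[labels == g, 1:2, drop = FALSE]
    if (nrow(pts) < 3L) {
      warning("group '", g, "' has fewer than 3 samples; ellipse skipped")
      next
    }
    S <- stats::cov(pts)
    out[[as.character(g)]] <- structure(
      list(group = g, center = colMeans(pts), covariance = S, level = level,
           radius2 = stats::qchisq(level, df = 2),
           singular = det(S) <= .Machine$double.eps * max(diag(S))^2),
      class = "group_ellipse")
  }
  out
}

#' Boundary points of a confidence ellipse
#'
#' @param e a `group_ellipse` from [ellipse95()].
#' @param n number of boundary points.
#' @return An n x 2 matrix tracing the ellipse.
#' @export
ellipse_points <- function(e, n = 100) {
  stopifnot(inherits(e, "group_ellipse"))
  eg <- eigen(e$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  axes <- sqrt(pmax(eg$values, 0) * e$radius2)
  circ <- cbind(axes[1] * cos(theta), axes[2] * sin(theta))
  sweep(circ %*% t(eg$vectors), 2, e$center, "+")
}

#' Group-separation summary of a PCA model
#'
#' Reports, per component, the group means and the standardized mean
#' difference between the two groups, identifies the component with the
#' largest standardized separation, and computes the mean silhouette width
#' of the grouping on the first component. Exploratory only: no significance
#' claim is attached.
#'
#' @param model a [fit_pca()] result.
#' @param labels group label per sample (exactly 2 distinct labels required
#'   for the separation statistics).
#' @return List of class `separation_report`: `group_means` (groups x
#'   components), `std_diff` per component, `best_component`,
#'   `pc1_silhouette`, `pc1_direction` (which group sits on the positive
#'   side of PC1), `pc1_overlap` (do the two groups' PC1 score ranges
#'   overlap).
#' @export
separation_report <- function(model, labels) {
  stopifnot(inherits(model, "pca_model"))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("separation needs at least 2 groups")
  sc <- model$scores
  gm <- t(vapply(groups, function(g) colMeans(sc[labels == g, , drop = FALSE]),
                 numeric(ncol(sc))))
  rownames(gm) <- groups
  std_diff <- if (length(groups) == 2L) {
    vapply(seq_len(ncol(sc)), function(k) {
      a <- sc[labels == groups[1], k]; b <- sc[labels == groups[2], k]
      sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
      if (sp == 0) return(if (gm[1, k] == gm[2, k]) 0 else Inf)
      abs(gm[1, k] - gm[2, k]) / sp
    }, numeric(1))
  } else {
    rep(NA_real_, ncol(sc))
  }
  pc1 <- sc[, 1]
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(pc1))
  a <- pc1[labels == groups[1]]; b <- pc1[labels == groups[2]]
  structure(list(
    group_means = gm,
    std_diff = std_diff,
    best_component = if (all(is.na(std_diff))) NA_integer_
                     else which.max(std_diff),
    pc1_silhouette = mean(sil[, "sil_width"]),
    pc1_direction = groups[which.max(gm[, 1])],
    pc1_overlap = length(groups) == 2L && max(min(a), min(b)) <= min(max(a), max(b))
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  cat(sprintf("  PC1 silhouette: %.3f; positive-PC1 group: %s; ranges %s\n",
              x$pc1_silhouette, x$pc1_direction,
              if (x$pc1_overlap) "overlap" else "do not overlap"))
  if (!is.na(x$best_component)) {
    cat(sprintf("  best-separating component: PC%d (standardized diff %.2f)\n",
                x$best_component, x$std_diff[x$best_component]))
  }
  invisible(x)
}

#' Read a particle size distribution table
#'
#' Expects a CSV with columns `sample_id`, `condition` and one numeric
#' column per size bin, the column name being the bin's particle size in
#' micrometres; one row per sample, cell values are volume densities.
#'
#' @param path CSV file path.
#' @return List of class `psd_table`: `X` (samples x bins matrix, bins
#'   ascending), `bins_um`, `sample_ids`, `condition`.
#' @export
read_psd_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df))) {
    stop("PSD table must have columns sample_id and condition")
  }
  bin_cols <- setdiff(names(df), need)
  bins <- suppressWarnings(as.numeric(bin_cols))
  if (anyNA(bins)) {
    stop("non-numeric size-bin column name(s): ",
         paste(bin_cols[is.na(bins)], collapse = ", "))
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("size bins must be strictly ascending (um): check column order")
  }
  X <- as.matrix(df[, bin_cols, drop = FALSE])
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative volume density at row %d, bin %s um",
                 bad[1], bin_cols[bad[2]]))
  }
  rownames(X) <- df$sample_id
  structure(list(X = X, bins_um = bins, sample_ids = df$sample_id,
                 condition = df$condition),
            class = "psd_table")
}
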