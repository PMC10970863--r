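test_that("autoscaling centers and scales to unit sample variance", {
  X <- cbind(a = c(3, 5, 7), b = c(1, 1, 4))
  sc <- autoscale(X)
  expect_equal(sc$X[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(sc$X), c(a = 0, b = 0))
  expect_equal(apply(sc$X, 2, sd), c(a = 1, b = 1))
  # idempotent to tolerance
  sc2 <- autoscale(sc$X)
  expect_equal(sc2$X, sc$X, tolerance = 1e-12)
  # constant columns are dropped and recorded
  expect_warning(scd <- autoscale(cbind(u = c(1, 2, 3), v = c(5, 5, 5))),
                 "zero-variance")
  expect_identical(colnames(scd$X), "u")
  expect_identical(scd$dropped, "v")
  expect_error(autoscale(cbind(c(2, 2), c(3, 3))), "zero variance")
  expect_error(autoscale(matrix(1, 1, 3)), "2 samples")
})

test_that("PCA matches the correlation-matrix eigendecomposition", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:10, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    sc <- autoscale(X)
    m <- fit_pca(sc)
    # eigen oracle: eigenvalues of the correlation matrix
    ev <- eigen(cor(X), symmetric = TRUE)$values
    k <- ncol(m$scores)
    expect_equal(m$singular_values^2 / (n - 1), ev[seq_len(k)],
                 tolerance = 1e-8)
    # loadings orthonormal; scores are projections; full reconstruction
    expect_equal(crossprod(m$loadings), diag(k), ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(m$scores, sc$X %*% m$loadings, ignore_attr = TRUE)
    expect_lt(norm(sc$X - m$scores %*% t(m$loadings), "F"), 1e-8)
    # explained variance: non-increasing, sums to 100 with all components
    # (the centered matrix has rank at most n - 1, so the retained set is
    # exhaustive)
    expect_true(all(diff(m$explained_variance_pct) <= 1e-12))
    expect_equal(sum(m$explained_variance_pct), 100, tolerance = 1e-8)
  }
})

test_that("rank-1 structure loads entirely on PC1", {
  x <- c(0.5, 1.8, 2.2, 3.9)
  X <- cbind(x, 2 * x + 3)
  m <- fit_pca(autoscale(X))
  expect_equal(m$explained_variance_pct[1], 100)
  expect_error(fit_pca(autoscale(X), n_components = 4), "exceeds")
})

test_that("scores are stable under reordering and the sign rule is fixed", {
  set.seed(202)
  X <- matrix(rnorm(60), 6, 10)
  sc <- autoscale(X)$X
  m1 <- fit_pca(sc)
  perm <- sample(6)
  m2 <- fit_pca(sc[perm, ])
  expect_equal(m2$explained_variance_pct, m1$explained_variance_pct)
  expect_equal(m2$scores, m1$scores[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # largest-|loading| element of every component is positive
  for (k in seq_len(ncol(m1$loadings))) {
    expect_gt(m1$loadings[which.max(abs(m1$loadings[, k])), k], 0)
  }
  # duplicated samples receive identical scores
  md <- fit_pca(autoscale(rbind(X, X[1, ])))
  expect_equal(md$scores[1, ], md$scores[7, ], tolerance = 1e-8)
})

test_that("confidence ellipses use the chi-square radius", {
  # points with exactly identity covariance -> circle of radius sqrt(5.991)
  pts <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(unname(cov(pts)), diag(2))
  e <- ellipse95(pts, rep("g", 4))$g
  expect_equal(e$center, c(0, 0), ignore_attr = TRUE)
  bound <- ellipse_points(e, 200)
  expect_equal(sqrt(rowSums(bound^2)),
               rep(sqrt(qchisq(0.95, 2)), 200), tolerance = 1e-8)
  # groups below 3 points are skipped with a warning
  expect_warning(es <- ellipse95(pts, c("g", "g", "g", "h")), "fewer than 3")
  expect_named(es, "g")
  # collinear scores are flagged singular
  col <- cbind(1:5, 2 * (1:5))
  expect_true(ellipse95(col, rep("c", 5))$c$singular)
  # empirical coverage of the 95% region on a known normal
  set.seed(303)
  z <- cbind(rnorm(4000, sd = 2), rnorm(4000))
  ez <- ellipse95(z, rep("n", 4000))$n
  ctr <- sweep(z, 2, ez$center)
  d2 <- rowSums((ctr %*% solve(ez$covariance)) * ctr)
  expect_equal(mean(d2 <= ez$radius2), 0.95, tolerance = 0.01)
})

test_that("separation reports quantify group structure on PC1", {
  set.seed(404)
  # two well-separated clusters in a 6-variable space
  A <- matrix(rnorm(5 * 6, mean = 0), 5, 6)
  B <- matrix(rnorm(5 * 6, mean = 4), 5, 6)
  X <- rbind(A, B)
  labs <- rep(c("IS", "OOS"), each = 5)
  m <- fit_pca(autoscale(X))
  rep1 <- separation_report(m, labs)
  expect_gt(rep1$pc1_silhouette, 0.5)
  expect_identical(rep1$best_component, 1L)
  # identical groups: no structure
  Y <- rbind(A, A + matrix(rnorm(30, sd = 1e-3), 5, 6))
  rep0 <- separation_report(fit_pca(autoscale(Y)), labs)
  expect_lt(abs(rep0$pc1_silhouette), 0.25)
  # permuting labels destroys the separation
  perm_labs <- sample(labs)
  repp <- separation_report(m, perm_labs)
  expect_lt(repp$pc1_silhouette, rep1$pc1_silhouette)
  expect_error(separation_report(m, rep("IS", 10)), "2 groups")
})

test_that("PSD tables parse with validation and separate families in PCA", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "psd.csv")
  writeLines(c("sample_id,condition,10,20,40",
               "s1,IS,10,70,20",
               "s2,OOS,5,35,60"), f)
  tab <- read_psd_table(f)
  expect_identical(dim(tab$X), c(2L, 3L))
  expect_identical(tab$bins_um, c(10, 20, 40))
  expect_equal(unname(rowSums(tab$X)), c(100, 100))
  # validation failures carry locations
  writeLines(c("sample_id,condition,20,10", "s1,IS,1,2"), f)
  expect_error(read_psd_table(f), "ascending")
  writeLines(c("sample_id,condition,10,20", "s1,IS,-1,2"), f)
  expect_error(read_psd_table(f), "negative volume density")
  # synthetic unimodal vs bimodal PSD families separate on PC1
  bins <- c(1, 2, 5, 10, 20, 40, 80, 120, 180, 280, 400)
  rows <- lapply(1:6, function(i) {
    spec <- if (i <= 3) is_particle_defaults(400) else oos_particle_defaults(400)
    psd_from_diameters(sample_diameters(spec, seed = 900 + i), bins)
  })
  X <- do.call(rbind, rows)
  labs <- rep(c("IS", "OOS"), each = 3)
  suppressWarnings(m <- fit_pca(autoscale(X)))
  repq <- separation_report(m, labs)
  expect_gt(repq$pc1_silhouette, 0.5)
  expect_false(repq$pc1_overlap)
})
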