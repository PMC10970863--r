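test_that("co-occurrence counts enumerate ordered pairs at the offset", {
  img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)))
  g <- glcm(img, c(0, 1), Ng = 2)
  expect_identical(g$counts, rbind(c(1L, 0L), c(0L, 1L)))
  expect_identical(g$R, 2L)
  expect_equal(sum(g$p), 1)
  # constant image: a single nonzero cell with p = 1
  cg <- glcm(gray_image(matrix(7L, 4, 4)), c(0, 1), Ng = 256)
  expect_identical(sum(cg$counts > 0), 1L)
  expect_equal(cg$p[8, 8], 1)
  expect_error(glcm(gray_image(matrix(0L, 1, 2)), c(0, 5)), "no pixel pairs")
})

test_that("co-occurrence matches exhaustive pair enumeration", {
  set.seed(31)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1), c(2, -3))
  for (rep in 1:12) {
    img <- rand_gray(16, 16, levels = 8)
    for (off in offsets) {
      g <- glcm(img, off, Ng = 8)
      expect_identical(g$counts, brute_glcm(img$pixels, off, 8L))
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
      expect_identical(g$R, sum(g$counts))
    }
  }
})

test_that("pair totals follow the offset geometry exactly", {
  set.seed(3)
  for (rep in 1:10) {
    H <- sample(4:12, 1); W <- sample(4:12, 1); D <- sample(1:3, 1)
    img <- rand_gray(H, W, levels = 4)
    expect_identical(glcm(img, c(0, D), Ng = 4)$R, H * (W - D))
    expect_identical(glcm(img, c(-D, 0), Ng = 4)$R, (H - D) * W)
    expect_identical(glcm(img, c(-D, D), Ng = 4)$R, (H - D) * (W - D))
    expect_identical(glcm(img, c(-D, -D), Ng = 4)$R, (H - D) * (W - D))
  }
})

test_that("descriptors reproduce closed forms", {
  # constant image: perfectly ordered, degenerate marginals trigger COR := 1
  h <- haralick(glcm(gray_image(matrix(9L, 5, 5)), c(0, 1)))
  expect_equal(unname(h), c(1, 0, 1, 0))
  # diagonal p = diag(0.5, 0.5)
  hd <- haralick(glcm(gray_image(rbind(c(0L, 0L), c(1L, 1L))), c(0, 1), Ng = 2))
  expect_equal(hd[["ASM"]], 0.5)
  expect_equal(hd[["CON"]], 0)
  expect_equal(hd[["COR"]], 1)
  expect_equal(hd[["ENT"]], log(2))
  # alternating strip: pairs (0,1), (1,0), (0,1)
  hs <- haralick(glcm(gray_image(matrix(c(0L, 1L, 0L, 1L), 1, 4)), c(0, 1), Ng = 2))
  expect_equal(hs[["ASM"]], 5 / 9)
  expect_equal(hs[["CON"]], 1)
  # entropy of a uniform distribution is log of the cell count
  unif <- structure(list(counts = matrix(1L, 4, 4), p = matrix(1 / 16, 4, 4),
                         R = 16L, Ng = 4L, offset = c(0L, 1L)),
                    class = "glcm")
  expect_equal(haralick(unif)[["ENT"]], log(16))
  expect_equal(haralick(unif, entropy_base = 2)[["ENT"]], 4)
  # the sigma = 0 convention fires exactly when a marginal is degenerate
  m <- marginal_stats(glcm(gray_image(matrix(9L, 5, 5)), c(0, 1)))
  expect_equal(m$sigma_x, 0)
  m2 <- marginal_stats(glcm(gray_image(rbind(c(0L, 0L), c(1L, 1L))), c(0, 1), Ng = 2))
  expect_gt(m2$sigma_x, 0)
  # unnormalized input is rejected
  bad <- unif; bad$p <- bad$p * 2
  expect_error(haralick(bad), "not normalized")
})

test_that("four-direction features respect offset geometry", {
  iso <- haralick_all_directions(gray_image(matrix(100L, 6, 6)))
  nums <- as.matrix(iso[, c("deg0", "deg45", "deg90", "deg135")])
  expect_true(all(nums == nums[, 1]))
  expect_equal(iso$mu, nums[, 1])
  # the 90-degree GLCM of an image is the 0-degree GLCM of its rotation
  set.seed(17)
  for (rep in 1:5) {
    img <- rand_gray(9, 7, levels = 6)
    rot <- gray_image(t(img$pixels[nrow(img$pixels):1, , drop = FALSE]))
    f <- haralick_all_directions(img, Ng = 6)
    fr <- haralick_all_directions(rot, Ng = 6)
    expect_equal(f$deg90, fr$deg0, tolerance = 1e-12)
  }
})

test_that("aggregation reproduces tabulated direction and condition means", {
  ref <- reference_haralick_table()
  # directional mean recomputed from the four printed directions
  a65_asm <- ref[ref$sample_id == "A0065" & ref$feature == "ASM", ]
  mu <- mean(as.numeric(a65_asm[, c("deg0", "deg45", "deg90", "deg135")]))
  expect_equal(powdertex:::round_half_up(mu, 3), 0.104)
  # condition-level mean of the per-sample directional means, OOS group
  oos <- ref[ref$condition == "OOS", ]
  cond_mu <- tapply(oos$mu, oos$feature, mean)
  expect_equal(powdertex:::round_half_up(cond_mu[["ASM"]], 3), 0.123)
  expect_equal(powdertex:::round_half_up(cond_mu[["CON"]], 3), 0.199)
  expect_equal(powdertex:::round_half_up(cond_mu[["COR"]], 3), 0.958)
  # the same arithmetic through aggregate_haralick()
  tabs <- lapply(unique(oos$sample_id), function(s) {
    structure(oos[oos$sample_id == s,
                  c("feature", "deg0", "deg45", "deg90", "deg135", "mu")],
              class = c("haralick_features", "data.frame"))
  })
  agg <- aggregate_haralick(tabs, level = "condition")
  expect_equal(powdertex:::round_half_up(agg$mu[agg$feature == "ASM"], 3), 0.123)
  expect_identical(attr(agg, "n_items"), 3L)
  # aggregation of one item is the identity
  one <- aggregate_haralick(tabs[1], level = "sample")
  expect_equal(one$mu, tabs[[1]]$mu)
  expect_error(aggregate_haralick(list()), "non-empty")
})

test_that("table export rounds half-up at 3 decimals", {
  f <- data.frame(feature = "ASM", deg0 = 0.10375, deg45 = 0.0005,
                  deg90 = 0.1, deg135 = 0.2, mu = 0.10375)
  class(f) <- c("haralick_features", "data.frame")
  out <- format_haralick(f)
  expect_equal(out$deg0, 0.104)
  expect_equal(out$deg45, 0.001)
})
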