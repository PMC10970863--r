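# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive quantities by exhaustive enumeration so the
# vectorized implementations are checked against something slower but
# transparently correct.

# box counting by scanning every aligned r x r tile at every dyadic scale
brute_box_count <- function(mask) {
  side <- 2^ceiling(log2(max(dim(mask))))
  pm <- matrix(FALSE, side, side)
  pm[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  r <- 2^(0:round(log2(side)))
  n <- vapply(r, function(rr) {
    cnt <- 0L
    for (i in seq(1, side, by = rr)) {
      for (j in seq(1, side, by = rr)) {
        if (any(pm[i:(i + rr - 1), j:(j + rr - 1)])) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
  list(r = r, n = n)
}

# GLCM by enumerating every pixel pair
brute_glcm <- function(pixels, offset, Ng) {
  H <- nrow(pixels); W <- ncol(pixels)
  counts <- matrix(0L, Ng, Ng)
  for (p in seq_len(H)) {
    for (q in seq_len(W)) {
      p2 <- p + offset[1]; q2 <- q + offset[2]
      if (p2 >= 1 && p2 <= H && q2 >= 1 && q2 <= W) {
        i <- pixels[p, q]; j <- pixels[p2, q2]
        counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1L
      }
    }
  }
  counts
}

rand_gray <- function(h, w, levels = 256) {
  gray_image(matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w))
}

rand_mask <- function(h, w, p = 0.3) {
  binary_image(matrix(stats::runif(h * w) < p, h, w))
}

# small default-condition ensembles shared by the slower tests
default_band_mean_fd <- function(img, band = c(20, 170)) {
  cur <- fd_threshold_curve(img)
  mean(cur$mean_fd[cur$threshold >= band[1] & cur$threshold <= band[2]])
}
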