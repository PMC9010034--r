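# Independent naive-loop oracles used to cross-check the vectorized
# implementations. These are deliberately written as direct transcriptions of
# the defining formulas (explicit loops, no shared code with the package
# internals).

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Brute-force patch cross-correlation: for each output site (i, j) and each
# displacement (a multiple of `stride` within `radius` strides), sum the
# products of the centered patch of F1 with the displaced patch of F2 over
# all patch offsets and channels (zero outside the image), divided by the
# channel count.
oracle_corr <- function(F1, F2, patch = c(3, 3), stride = 3, radius = 1) {
  H <- dim(F1)[1]; W <- dim(F1)[2]; C <- dim(F1)[3]
  ph <- (patch[1] - 1) %/% 2; pw <- (patch[2] - 1) %/% 2
  disp <- expand.grid(dx = stride * (-radius:radius),
                      dy = stride * (-radius:radius))[, c("dy", "dx")]
  out <- array(0, c(H, W, nrow(disp)))
  at <- function(F, c, i, j) {
    if (i >= 1 && i <= H && j >= 1 && j <= W) F[i, j, c] else 0
  }
  for (d in seq_len(nrow(disp))) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- 0
      for (c in seq_len(C))
        for (a in -ph:ph) for (b in -pw:pw)
          acc <- acc + at(F1, c, i + a, j + b) *
            at(F2, c, i + a + disp$dy[d], j + b + disp$dx[d])
      out[i, j, d] <- acc / C
    }
  }
  out
}

# Naive two-pass population standard deviation.
oracle_std <- function(v) {
  n <- length(v)
  m <- 0
  for (x in v) m <- m + x / n
  s <- 0
  for (x in v) s <- s + (x - m)^2 / n
  sqrt(s)
}

# Naive forward-difference average gradient over the interior grid.
oracle_ag <- function(M) {
  m <- nrow(M); n <- ncol(M)
  acc <- 0
  for (i in 1:(m - 1)) for (j in 1:(n - 1)) {
    dx <- M[i, j + 1] - M[i, j]
    dy <- M[i + 1, j] - M[i, j]
    acc <- acc + sqrt((dx^2 + dy^2) / 2)
  }
  acc / ((m - 1) * (n - 1))
}

# Naive binned entropy, natural log.
oracle_entropy <- function(v, n_bins = 256) {
  counts <- integer(n_bins)
  for (x in v) {
    b <- min(max(floor(x * n_bins) + 1, 1), n_bins)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(v)
  -sum(p * log(p))
}

oracle_rmse <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  sqrt(acc / length(x))
}

# Adaptive average pooling by explicit window means.
oracle_block_pool <- function(M, s) {
  H <- nrow(M); bh <- H %/% s; bw <- ncol(M) %/% s
  out <- matrix(0, s, s)
  for (i in seq_len(s)) for (j in seq_len(s))
    out[i, j] <- mean(M[((i - 1) * bh + 1):(i * bh), ((j - 1) * bw + 1):(j * bw)])
  out
}

# Pixel-domain VIF transcribed with explicit per-window loops (scalar GSM);
# identical algorithm, independent evaluation path.
oracle_vif <- function(ref, dist, sigma_nsq = 2, scales = 2) {
  eps <- 1e-10
  gwin <- function(N) {
    k <- exp(-((seq_len(N) - (N + 1) / 2)^2) / (2 * (N / 5)^2))
    w <- outer(k, k); w / sum(w)
  }
  conv_valid <- function(M, win) {
    N <- nrow(win)
    H <- nrow(M) - N + 1; W <- ncol(M) - N + 1
    out <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W))
      out[i, j] <- sum(M[i:(i + N - 1), j:(j + N - 1)] * win)
    out
  }
  num <- 0; den <- 0
  for (scale in seq_len(scales)) {
    N <- 2^(scales - scale + 1) + 1
    win <- gwin(N)
    if (scale > 1) {
      ref <- conv_valid(ref, win)[seq(1, nrow(ref) - N + 1, 2),
                                  seq(1, ncol(ref) - N + 1, 2), drop = FALSE]
      dist <- conv_valid(dist, win)[seq(1, nrow(dist) - N + 1, 2),
                                    seq(1, ncol(dist) - N + 1, 2), drop = FALSE]
    }
    mu1 <- conv_valid(ref, win); mu2 <- conv_valid(dist, win)
    s1 <- conv_valid(ref * ref, win) - mu1^2
    s2 <- conv_valid(dist * dist, win) - mu2^2
    s12 <- conv_valid(ref * dist, win) - mu1 * mu2
    s1[s1 < 0] <- 0; s2[s2 < 0] <- 0
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log(1 + s1 / sigma_nsq))
  }
  num / den
}

# 8-connected components of a logical mask by flood fill.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      n <- n + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- n
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) &&
              mask[i, j] && lab[i, j] == 0L) {
            lab[i, j] <- n
            queue[[length(queue) + 1]] <- c(i, j)
          }
        }
      }
    }
  }
  n
}

# Small model configuration used across tests (input sizes divisible by 8).
tiny_model_config <- function(...) {
  model_config(stem_channels = 8L, mlp_reduction = 4L, spp_scales = c(8L, 4L, 2L, 1L),
               branch_channels = 4L, decoder_channels = c(8L, 4L, 1L), ...)
}
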