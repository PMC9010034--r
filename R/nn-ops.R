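# Low-level vectorized tensor primitives.
#
# Feature maps are numeric arrays dim = c(H, W, C); kernels are arrays
# dim = c(kh, kw, Cin, Cout) with odd kh, kw. All convolutions are SAME
# (zero padded), stride 1, so spatial size is conserved through every stage.
# Convolutions are evaluated as sums of shifted elementwise products, which
# keeps every inner operation a single vectorized matrix op.

# out[i, j] = M[i + dy, j + dx], zero outside the support.
shift_mat <- function(M, dy, dx) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  i0 <- max(1L, 1L - dy); i1 <- min(H, H - dy)
  j0 <- max(1L, 1L - dx); j1 <- min(W, W - dx)
  if (i0 <= i1 && j0 <= j1)
    out[i0:i1, j0:j1] <- M[(i0 + dy):(i1 + dy), (j0 + dx):(j1 + dx)]
  out
}

as_fmap <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# channel c of an H x W x C array as an H x W matrix (no dimension dropping)
chan <- function(X, c) matrix(X[, , c], dim(X)[1L], dim(X)[2L])

# SAME cross-correlation ("conv" in the deep-learning sense), stride 1.
conv2d_same <- function(X, W, b = NULL) {
  X <- as_fmap(X)
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  stopifnot(dim(X)[3] == cin, kh %% 2L == 1L, kw %% 2L == 1L)
  H <- dim(X)[1]; Wd <- dim(X)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  # Pre-shift every input channel once per kernel offset.
  Xs <- vector("list", cin)
  for (c in seq_len(cin)) {
    Xs[[c]] <- vector("list", kh * kw)
    idx <- 1L
    for (a in -ph:ph) for (d in -pw:pw) {
      Xs[[c]][[idx]] <- shift_mat(chan(X, c), a, d)
      idx <- idx + 1L
    }
  }
  out <- array(0, c(H, Wd, cout))
  for (k in seq_len(cout)) {
    acc <- matrix(if (is.null(b)) 0 else b[k], H, Wd)
    for (c in seq_len(cin)) {
      idx <- 1L
      for (a in seq_len(kh)) for (d in seq_len(kw)) {
        w <- W[a, d, c, k]
        if (w != 0) acc <- acc + w * Xs[[c]][[idx]]
        idx <- idx + 1L
      }
    }
    out[, , k] <- acc
  }
  out
}

# Backward pass of conv2d_same. G has dim c(H, W, Cout).
# Returns list(dX, dW, db).
conv2d_same_bwd <- function(X, W, G) {
  X <- as_fmap(X); G <- as_fmap(G)
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- dim(X)[1]; Wd <- dim(X)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dW <- array(0, dim(W))
  db <- numeric(cout)
  dX <- array(0, dim(X))
  # shifted gradients: Gs[[k]][[idx]] = shift(G_k, -a, -d)
  Gs <- vector("list", cout)
  for (k in seq_len(cout)) {
    db[k] <- sum(G[, , k])
    Gs[[k]] <- vector("list", kh * kw)
    idx <- 1L
    for (a in -ph:ph) for (d in -pw:pw) {
      Gs[[k]][[idx]] <- shift_mat(chan(G, k), -a, -d)
      idx <- idx + 1L
    }
  }
  for (c in seq_len(cin)) {
    Xc <- chan(X, c)
    dXc <- matrix(0, H, Wd)
    for (k in seq_len(cout)) {
      Gk <- chan(G, k)
      idx <- 1L
      for (a in -ph:ph) for (d in -pw:pw) {
        dW[a + ph + 1L, d + pw + 1L, c, k] <- sum(shift_mat(Xc, a, d) * Gk)
        w <- W[a + ph + 1L, d + pw + 1L, c, k]
        if (w != 0) dXc <- dXc + w * Gs[[k]][[idx]]
        idx <- idx + 1L
      }
    }
    dX[, , c] <- dXc
  }
  list(dX = dX, dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)
relu_bwd <- function(pre, g) g * (pre > 0)
sigmoid_ <- function(x) 1 / (1 + exp(-x))

# Adaptive average pooling of an H x H map onto an s x s grid; requires H, W
# divisible by s (enforced upstream), i.e. exact block averaging.
block_pool <- function(M, s) {
  H <- nrow(M); W <- ncol(M)
  stopifnot(H %% s == 0L, W %% s == 0L)
  bh <- H %/% s; bw <- W %/% s
  # average over bh x bw blocks via row/col group sums
  rowg <- rowsum(M, rep(seq_len(s), each = bh)) / bh
  out <- t(rowsum(t(rowg), rep(seq_len(s), each = bw)) / bw)
  dimnames(out) <- NULL
  out
}

block_pool_bwd <- function(G, H, W) {
  s <- nrow(G)
  bh <- H %/% s; bw <- W %/% s
  G[rep(seq_len(s), each = bh), rep(seq_len(s), each = bw), drop = FALSE] / (bh * bw)
}

# Bilinear upsampling of a matrix to H x W (pixel-center convention shared
# with resample_to()); returns the map and, for backward, use the transposed
# interpolation matrices.
upsample_bilinear <- function(M, H, W) {
  interp_matrix(nrow(M), H, "bilinear") %*% M %*%
    t(interp_matrix(ncol(M), W, "bilinear"))
}

upsample_bilinear_bwd <- function(G, h_in, w_in) {
  t(interp_matrix(h_in, nrow(G), "bilinear")) %*% G %*%
    interp_matrix(w_in, ncol(G), "bilinear")
}

# Normalized 1-D Gaussian kernel, radius 3*sigma.
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable zero-padded Gaussian blur of a matrix.
gauss_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  tmp <- matrix(0, nrow(M), ncol(M))
  for (o in -r:r) tmp <- tmp + k[o + r + 1L] * shift_mat(M, o, 0L)
  out <- matrix(0, nrow(M), ncol(M))
  for (o in -r:r) out <- out + k[o + r + 1L] * shift_mat(tmp, 0L, o)
  out
}

# Valid 2-D separable correlation with an explicit (non-separable OK) window;
# used by the VIF metric. Window dims must be odd.
filter2_valid <- function(M, win) {
  kh <- nrow(win); kw <- ncol(win)
  H <- nrow(M) - kh + 1L; W <- ncol(M) - kw + 1L
  if (H < 1L || W < 1L) stop("filter2_valid: window larger than image", call. = FALSE)
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) for (d in seq_len(kw)) {
    w <- win[a, d]
    if (w != 0) out <- out + w * M[a:(a + H - 1L), d:(d + W - 1L)]
  }
  out
}

# Restore-on-exit seeded evaluation so generators are deterministic without
# clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}
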