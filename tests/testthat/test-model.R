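test_that("Xavier initialization is deterministic, seed-sensitive, correctly scaled", {
  cfg <- model_config()
  p1 <- init_parameters(cfg, seed = 5)
  p2 <- init_parameters(cfg, seed = 5)
  p3 <- init_parameters(cfg, seed = 6)
  expect_identical(p1$tensors, p2$tensors)
  expect_false(identical(p1$tensors, p3$tensors))
  expect_true(all(p1$tensors$stem_b == 0))

  # empirical variance of the stem kernel (fan_in 9, fan_out 9*16) over
  # enough draws, against the Glorot target 2 / (fan_in + fan_out)
  draws <- unlist(lapply(1:70, function(s) init_parameters(cfg, s)$tensors$stem_W))
  expect_gt(length(draws), 1e4)
  target <- 2 / (9 + 9 * 16)
  expect_lt(abs(var(draws) - target) / target, 0.2)
})

test_that("convolution primitive matches a hand computation and its backward matches finite differences", {
  # single 3x3 kernel of ones on a one-hot 5x5 image: 3x3 plateau of ones
  X <- array(0, c(5, 5, 1)); X[3, 3, 1] <- 1
  W <- array(1, c(3, 3, 1, 1))
  out <- spfn:::conv2d_same(X, W, 0)
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1
  expect_equal(out[, , 1], expected)

  set.seed(1)
  X <- array(runif(6 * 6 * 2), c(6, 6, 2))
  W <- array(rnorm(3 * 3 * 2 * 3, 0, 0.3), c(3, 3, 2, 3))
  b <- rnorm(3)
  G <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  loss <- function(X, W, b) sum(spfn:::conv2d_same(X, W, b) * G)
  bwd <- spfn:::conv2d_same_bwd(X, W, G)
  eps <- 1e-6
  for (idx in c(1, 20, 50)) {
    Wp <- W; Wp[idx] <- W[idx] + eps; Wm <- W; Wm[idx] <- W[idx] - eps
    expect_equal(bwd$dW[idx], (loss(X, Wp, b) - loss(X, Wm, b)) / (2 * eps),
                 tolerance = 1e-5)
    Xp <- X; Xp[idx] <- X[idx] + eps; Xm <- X; Xm[idx] <- X[idx] - eps
    expect_equal(bwd$dX[idx], (loss(Xp, W, b) - loss(Xm, W, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("channel coupling gates follow the sigmoid construction", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 1)
  F <- spfn:::as_fmap(array(runif(16 * 16 * 8), c(16, 16, 8)))

  gated <- channel_coupling(F, params)
  g <- attr(gated, "gate")
  expect_true(all(g > 0 & g < 1))
  expect_equal(dim(gated), dim(F))

  # zero MLP weights force every gate to sigmoid(0) = 0.5
  p0 <- params
  for (nm in c("cc_W1", "cc_b1", "cc_W2", "cc_b2"))
    p0$tensors[[nm]][] <- 0
  gated0 <- channel_coupling(F, p0)
  expect_equal(attr(gated0, "gate"), rep(0.5, 8))
  expect_equal(as.numeric(gated0), as.numeric(0.5 * F))

  # constant channels: global average and max pooling coincide
  Fc <- array(rep(seq(0.1, 0.8, by = 0.1), each = 16 * 16), c(16, 16, 8))
  cc <- spfn:::cc_forward(Fc, params)
  expect_equal(cc$gap, cc$gmp)
})

test_that("spatial pyramid pooling grids match the explicit window-average oracle", {
  for (s in c(16, 4, 2, 1)) {
    M <- rand_img(32, 32, s)
    expect_equal(spfn:::block_pool(M, s), oracle_block_pool(M, s), tolerance = 1e-12)
  }
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 2)
  Fp <- array(runif(16 * 16 * 8), c(16, 16, 8))
  Fs <- spatial_pyramid_coupling(Fp, params)
  expect_equal(dim(Fs), c(16L, 16L, 4L * cfg$branch_channels))
  # the scale-1 branch of a constant map broadcasts its average
  pooled <- spfn:::block_pool(matrix(0.3, 16, 16), 1)
  expect_equal(as.numeric(pooled), 0.3)
})

test_that("encoding concatenates gated, pyramid and raw channels; zero in, zero out", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 3)
  img <- image2d(rand_img(16, 16, 7), normalized = TRUE)
  enc <- encode(img, params)
  expect_equal(dim(enc), c(16L, 16L, cfg$stem_channels +
                             4L * cfg$branch_channels + 1L))
  expect_equal(enc[, , dim(enc)[3]], img$values)   # raw image channel

  z <- encode(image2d(matrix(0, 16, 16), normalized = TRUE), params)
  expect_equal(max(abs(z)), 0)

  expect_error(encode(image2d(matrix(2, 16, 16)), params), "normalized")
  expect_error(encode(image2d(matrix(0.5, 10, 10), normalized = TRUE), params),
               "spp_scales")
})

test_that("siamese branches share weights; untied mode breaks the sharing", {
  img <- image2d(rand_img(16, 16, 11), normalized = TRUE)
  tied <- init_parameters(tiny_model_config(), 4)
  expect_identical(encode(img, tied, "ct"), encode(img, tied, "pet"))

  untied <- init_parameters(tiny_model_config(untied = TRUE), 4)
  expect_false(identical(encode(img, untied, "ct"), encode(img, untied, "pet")))
})

test_that("cross-correlation layer obeys the one-hot, symmetry and oracle checks", {
  cfg0 <- model_config(corr_window_radius = 0L)
  hot <- array(0, c(9, 9, 1)); hot[5, 5, 1] <- 1
  resp <- cross_correlation_fuse(hot, hot, cfg0)
  expect_equal(resp[5, 5, 1], 1)
  far <- abs(row(resp[, , 1]) - 5) > 1 | abs(col(resp[, , 1]) - 5) > 1
  expect_equal(max(abs(resp[, , 1][far])), 0)

  # zero-displacement correlation is symmetric in its arguments
  set.seed(8)
  A <- array(runif(8 * 8 * 2), c(8, 8, 2))
  B <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_equal(cross_correlation_fuse(A, B, cfg0),
               cross_correlation_fuse(B, A, cfg0))

  # brute-force oracle, radius 1, stride 3
  cfg1 <- model_config()
  r <- cross_correlation_fuse(A, B, cfg1)
  expect_equal(r, oracle_corr(A, B, c(3, 3), 3, 1), tolerance = 1e-10)

  expect_error(cross_correlation_fuse(A, array(0, c(4, 4, 2)), cfg1), "shape")
})

test_that("decoder output is bounded and centered for zero features", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 5)
  Fpc <- array(rnorm(16 * 16 * 9), c(16, 16, 9))
  out <- decode(Fpc, params)
  expect_s3_class(out, "image2d")
  expect_true(all(out$values >= 0 & out$values <= 1))
  expect_equal(dim(out$values), c(16L, 16L))

  p0 <- params
  for (nm in names(p0$tensors)) p0$tensors[[nm]][] <- 0
  z <- decode(array(0, c(16, 16, 9)), p0)
  expect_equal(z$values, matrix(0.5, 16, 16))   # sigmoid(0)
})

test_that("fusion is deterministic, shape/range conserving, and branch-symmetric for identical inputs", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 6)
  pc <- phantom_config(ct_size = 32, seed = 1)
  pair <- phantom_to_pair(generate_dataset(1, pc)[[1]])
  f1 <- fuse(pair, params)
  f2 <- fuse(pair, params)
  expect_identical(f1$values, f2$values)
  expect_equal(dim(f1$values), dim(pair$ct$values))
  expect_true(all(f1$values >= 0 & f1$values <= 1))

  # identical inputs: swapping the branches changes nothing
  same <- image_pair(pair$ct, pair$ct)
  expect_identical(fuse(same, params)$values,
                   fuse(image_pair(pair$ct, pair$ct), params)$values)

  # radius 0: zero-displacement symmetry makes fuse(ct, pet) = fuse(pet, ct)
  cfg0 <- tiny_model_config(corr_window_radius = 0L)
  p0 <- init_parameters(cfg0, 6)
  swapped <- image_pair(pair$pet, pair$ct)
  expect_equal(fuse(pair, p0)$values, fuse(swapped, p0)$values, tolerance = 1e-12)
})

test_that("the correlation layer holds no trainable weights and checkpoints round-trip bitwise", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 7)
  expect_false(any(grepl("corr", names(params$tensors))))

  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(back$tensors, params$tensors)
  pc <- phantom_config(ct_size = 32, seed = 2)
  pair <- phantom_to_pair(generate_dataset(1, pc)[[1]])
  expect_identical(fuse(pair, params)$values, fuse(pair, back)$values)
})

test_that("every stage stays finite on degenerate inputs", {
  cfg <- tiny_model_config()
  params <- init_parameters(cfg, 8)
  for (img in list(matrix(0, 16, 16), matrix(1, 16, 16), rand_img(16, 16, 3))) {
    pair <- image_pair(image2d(img, normalized = TRUE),
                       image2d(img, normalized = TRUE))
    fw <- spfn:::fuse_forward(img, img, params)
    expect_true(all(is.finite(fw$enc_ct$out)))
    expect_true(all(is.finite(fw$corr$out)))
    expect_true(all(is.finite(fw$fused)))
  }
})
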