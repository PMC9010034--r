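# Reverse-mode gradients through every stage of the network, mirroring the
# cache-carrying forward functions in model.R. Gradients for the shared
# (siamese) encoder are the sum of both branches' contributions.

zero_grads <- function(params) {
  lapply(params$tensors, function(t) array(0, dim(as.array(t))))
}

add_grad <- function(grads, name, g) {
  grads[[name]] <- grads[[name]] + g
  grads
}

dec_backward <- function(cache, dfused, params) {
  t <- params$tensors
  fused <- sigmoid_(cache$pre3[, , 1L])
  dpre3 <- array(dfused * fused * (1 - fused), c(dim(dfused), 1L))
  b3 <- conv2d_same_bwd(cache$a2, t$dec3_W, dpre3)
  dpre2 <- relu_bwd(cache$pre2, b3$dX)
  b2 <- conv2d_same_bwd(cache$a1, t$dec2_W, dpre2)
  dpre1 <- relu_bwd(cache$pre1, b2$dX)
  b1 <- conv2d_same_bwd(cache$Fpc, t$dec1_W, dpre1)
  list(grads = list(dec1_W = b1$dW, dec1_b = b1$db,
                    dec2_W = b2$dW, dec2_b = b2$db,
                    dec3_W = b3$dW, dec3_b = b3$db),
       dFpc = b1$dX)
}

corr_backward <- function(cache, dOut) {
  F1 <- cache$F1; F2 <- cache$F2
  C <- dim(F1)[3]
  dF1 <- array(0, dim(F1)); dF2 <- array(0, dim(F2))
  for (di in seq_len(nrow(cache$disp))) {
    dy <- cache$disp$dy[di]; dx <- cache$disp$dx[di]
    dResp <- dOut[, , di]
    dQ <- matrix(0, nrow(dResp), ncol(dResp))
    for (a in -cache$ph:cache$ph) for (b in -cache$pw:cache$pw)
      dQ <- dQ + shift_mat(dResp, -a, -b)
    dQ <- dQ / C
    for (c in seq_len(C)) {
      dF1[, , c] <- chan(dF1, c) + dQ * shift_mat(chan(F2, c), dy, dx)
      dF2[, , c] <- chan(dF2, c) + shift_mat(dQ * chan(F1, c), -dy, -dx)
    }
  }
  list(dF1 = dF1, dF2 = dF2)
}

spp_backward <- function(cache, dFs, params, branch) {
  p <- branch_prefix(params, branch); t <- params$tensors
  cfg <- params$config
  H <- dim(cache$Fp)[1]; W <- dim(cache$Fp)[2]
  B <- dim(cache$inner)[3]
  grads <- list()
  dInner <- array(0, dim(cache$inner))
  for (i in seq_along(cfg$spp_scales)) {
    s <- cfg$spp_scales[i]
    br <- cache$branches[[i]]
    dUp <- dFs[, , ((i - 1L) * B + 1L):(i * B), drop = FALSE]
    dAct <- array(0, c(s, s, B))
    for (c in seq_len(B)) dAct[, , c] <- upsample_bilinear_bwd(chan(dUp, c), s, s)
    dPre <- relu_bwd(br$pre, dAct)
    bb <- conv2d_same_bwd(br$pooled, t[[sprintf("%sspp_s%d_W", p, s)]], dPre)
    grads[[sprintf("%sspp_s%d_W", p, s)]] <- bb$dW
    grads[[sprintf("%sspp_s%d_b", p, s)]] <- bb$db
    for (c in seq_len(B))
      dInner[, , c] <- chan(dInner, c) + block_pool_bwd(chan(bb$dX, c), H, W)
  }
  dInnerPre <- relu_bwd(cache$inner_pre, dInner)
  bin <- conv2d_same_bwd(cache$Fp, t[[paste0(p, "spp_in_W")]], dInnerPre)
  grads[[paste0(p, "spp_in_W")]] <- bin$dW
  grads[[paste0(p, "spp_in_b")]] <- bin$db
  list(grads = grads, dFp = bin$dX)
}

cc_backward <- function(cache, dFp, params, branch) {
  p <- branch_prefix(params, branch); t <- params$tensors
  F <- cache$F
  H <- dim(F)[1]; W <- dim(F)[2]; C <- dim(F)[3]
  gate <- cache$gate
  dF <- dFp * rep(gate, each = H * W)
  dgate <- vapply(seq_len(C), function(c) sum(dFp[, , c] * F[, , c]), numeric(1))
  dz <- dgate * gate * (1 - gate)
  W2 <- t[[paste0(p, "cc_W2")]]; W1 <- t[[paste0(p, "cc_W1")]]
  dW2 <- outer(dz, cache$ha + cache$hm)
  db2 <- 2 * dz
  dh <- as.vector(crossprod(W2, dz))
  dz1a <- dh * (cache$z1a > 0)
  dz1m <- dh * (cache$z1m > 0)
  dW1 <- outer(dz1a, cache$gap) + outer(dz1m, cache$gmp)
  db1 <- dz1a + dz1m
  dgap <- as.vector(crossprod(W1, dz1a))
  dgmp <- as.vector(crossprod(W1, dz1m))
  for (c in seq_len(C)) {
    dFc <- dF[, , c] + dgap[c] / (H * W)
    dFc[cache$amax[c]] <- dFc[cache$amax[c]] + dgmp[c]
    dF[, , c] <- dFc
  }
  grads <- stats::setNames(list(dW1, db1, dW2, db2),
                           paste0(p, c("cc_W1", "cc_b1", "cc_W2", "cc_b2")))
  list(grads = grads, dF = dF)
}

encode_backward <- function(cache, dOut, params, branch) {
  p <- branch_prefix(params, branch); t <- params$tensors
  C1 <- dim(cache$cc$out)[3]; C2 <- dim(cache$spp$out)[3]
  dFp_direct <- dOut[, , seq_len(C1), drop = FALSE]
  dFs <- dOut[, , C1 + seq_len(C2), drop = FALSE]
  sb <- spp_backward(cache$spp, dFs, params, branch)
  dFp <- dFp_direct + sb$dFp
  cb <- cc_backward(cache$cc, dFp, params, branch)
  dStemPre <- relu_bwd(cache$stem$pre, cb$dF)
  stb <- conv2d_same_bwd(array(cache$x, c(dim(cache$x), 1L)),
                         t[[paste0(p, "stem_W")]], dStemPre)
  grads <- c(sb$grads, cb$grads)
  grads[[paste0(p, "stem_W")]] <- stb$dW
  grads[[paste0(p, "stem_b")]] <- stb$db
  grads
}

# Full-network gradient of a scalar loss with dLoss/dfused supplied.
fuse_backward <- function(fw, dfused, params) {
  grads <- zero_grads(params)
  db <- dec_backward(fw$dec, dfused, params)
  for (nm in names(db$grads)) grads <- add_grad(grads, nm, db$grads[[nm]])
  cb <- corr_backward(fw$corr, db$dFpc)
  g_ct <- encode_backward(fw$enc_ct, cb$dF1, params, "ct")
  g_pet <- encode_backward(fw$enc_pet, cb$dF2, params, "pet")
  for (nm in names(g_ct)) grads <- add_grad(grads, nm, g_ct[[nm]])
  for (nm in names(g_pet)) grads <- add_grad(grads, nm, g_pet[[nm]])
  grads
}

# Loss (SSIM terms only) and parameter gradients for one pair.
pair_loss_grads <- function(pair, params, loss_cfg = ssim_config()) {
  ct <- pair$ct$values; pet <- pair$pet$values
  fw <- fuse_forward(ct, pet, params)
  s_ct <- ssim_stat(ct, fw$fused, loss_cfg)
  s_pet <- ssim_stat(pet, fw$fused, loss_cfg)
  dfused <- -ssim_grad_global(ct, fw$fused, loss_cfg) -
    ssim_grad_global(pet, fw$fused, loss_cfg)
  list(loss = 2 - s_ct - s_pet, ssim_ct = s_ct, ssim_pet = s_pet,
       grads = fuse_backward(fw, dfused, params), fused = fw$fused)
}
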