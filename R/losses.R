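#' SSIM configuration
#'
#' Constants and mode of the structural-similarity index used as the training
#' objective. With normalized images the dynamic range is `L = 1`, so
#' `C1 = (k1 L)^2 = 1e-4` and `C2 = (k2 L)^2 = 9e-4` at the defaults
#' `k1 = 0.01`, `k2 = 0.03`. `mode = "global"` (default) computes the means,
#' variances and covariance over the whole image; `mode = "windowed"`
#' averages the local SSIM map over sliding Gaussian windows (the usual
#' image-quality convention), provided because whole-image SSIM is an unusual
#' training signal.
#'
#' @param k1,k2 Stabilizing constants (> 0).
#' @param L Dynamic range of the images (1 for normalized input).
#' @param mode `"global"` or `"windowed"`.
#' @param window_size,window_sigma Gaussian window (windowed mode only).
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(k1 = 0.01, k2 = 0.03, L = 1,
                        mode = c("global", "windowed"),
                        window_size = 11L, window_sigma = 1.5) {
  mode <- match.arg(mode)
  if (k1 <= 0 || k2 <= 0 || L <= 0)
    stop("ssim_config: k1, k2, L must be > 0", call. = FALSE)
  if (window_size %% 2L == 0L || window_size < 3L)
    stop("ssim_config: window_size must be odd and >= 3", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, L = L, mode = mode,
                 C1 = (k1 * L)^2, C2 = (k2 * L)^2,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma),
            class = "ssim_config")
}

gauss_window2d <- function(size, sigma) {
  k <- exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sigma^2))
  w <- outer(k, k)
  w / sum(w)
}

ssim_global <- function(x, y, cfg) {
  mux <- mean(x); muy <- mean(y)
  sx2 <- mean((x - mux)^2); sy2 <- mean((y - muy)^2)
  sxy <- mean((x - mux) * (y - muy))
  ((2 * mux * muy + cfg$C1) / (mux^2 + muy^2 + cfg$C1)) *
    ((2 * sxy + cfg$C2) / (sx2 + sy2 + cfg$C2))
}

ssim_windowed <- function(x, y, cfg) {
  win <- gauss_window2d(cfg$window_size, cfg$window_sigma)
  mu1 <- filter2_valid(x, win); mu2 <- filter2_valid(y, win)
  s11 <- filter2_valid(x * x, win) - mu1^2
  s22 <- filter2_valid(y * y, win) - mu2^2
  s12 <- filter2_valid(x * y, win) - mu1 * mu2
  mean(((2 * mu1 * mu2 + cfg$C1) * (2 * s12 + cfg$C2)) /
       ((mu1^2 + mu2^2 + cfg$C1) * (s11 + s22 + cfg$C2)))
}

# scalar SSIM on bare matrices, honoring cfg$mode
ssim_stat <- function(x, y, cfg) {
  if (cfg$mode == "global") ssim_global(x, y, cfg) else ssim_windowed(x, y, cfg)
}

#' Structural similarity index
#'
#' `SSIM(x, y)` as a luminance x contrast/structure product. Symmetric in its
#' arguments, equal to 1 iff the images are identical, and bounded in
#' \[-1, 1\].
#'
#' @param x,y Same-shape images (`image2d` or numeric matrices).
#' @param cfg An [ssim_config()].
#' @return Scalar SSIM value.
#' @export
ssim <- function(x, y, cfg = ssim_config()) {
  xv <- as_values(x); yv <- as_values(y)
  if (!identical(dim(xv), dim(yv)))
    stop("ssim: image shapes differ", call. = FALSE)
  ssim_stat(xv, yv, cfg)
}

#' SSIM loss
#'
#' `1 - SSIM(x, y)`: zero iff the images are structurally identical, bounded
#' in \[0, 2\].
#'
#' @inheritParams ssim
#' @return Scalar loss.
#' @export
ssim_loss <- function(x, y, cfg = ssim_config()) 1 - ssim(x, y, cfg)

# dSSIM(x, y)/dy for the global (whole-image moments) mode; x held fixed.
ssim_grad_global <- function(x, y, cfg) {
  N <- length(y)
  mux <- mean(x); muy <- mean(y)
  sx2 <- mean((x - mux)^2); sy2 <- mean((y - muy)^2)
  sxy <- mean((x - mux) * (y - muy))
  la <- 2 * mux * muy + cfg$C1; lb <- mux^2 + muy^2 + cfg$C1
  ca <- 2 * sxy + cfg$C2; cb <- sx2 + sy2 + cfg$C2
  A <- la / lb; B <- ca / cb
  dA_dmuy <- (2 * mux * lb - la * 2 * muy) / lb^2
  # per-pixel: dmuy/dyi = 1/N, dsxy/dyi = (xi - mux)/N, dsy2/dyi = 2(yi - muy)/N
  dB <- (2 * (x - mux) * cb - ca * 2 * (y - muy)) / cb^2 / N
  dA <- dA_dmuy / N
  dA * B + A * dB
}

#' L1 norm of all model weights
#'
#' The regularization term of the training objective: the sum of absolute
#' values over every parameter tensor.
#'
#' @param params An `spfn_params` object.
#' @return Scalar `sum(|w|)`.
#' @export
l1_norm <- function(params) {
  stopifnot(inherits(params, "spfn_params"))
  sum(vapply(params$tensors, function(t) sum(abs(t)), numeric(1)))
}

#' Fusion training objective
#'
#' The self-supervised two-source loss
#' `total = (1 - SSIM(ct, fused)) + (1 - SSIM(pet, fused)) + lambda * sum(|w|)`:
#' the fused image is pushed toward structural similarity with both sources
#' while the L1 weight penalty discourages noisy reconstructions and
#' overfitting. The unweighted literal objective is recovered with
#' `lambda = 1`; the default `lambda = 1e-4` keeps the penalty from dominating
#' the bounded SSIM terms for realistically sized networks.
#'
#' An image-domain reading of the regularizer — a penalty on the mean absolute
#' deviation of the fused image from the source average — is available behind
#' `image_l1_weight` (default 0, off); it is an alternative interpretation of
#' the L1 term, not part of the weight-penalty objective.
#'
#' @param ct,pet,fused Same-shape normalized images.
#' @param params Optional `spfn_params`; when `NULL` the L1 term is 0.
#' @param lambda Regularization weight (>= 0).
#' @param cfg An [ssim_config()].
#' @param image_l1_weight Optional weight for the image-domain L1 term
#'   `mean(|fused - (ct + pet)/2|)`.
#' @return An object of class `loss_value` with elements `total`, `ssim_ct`,
#'   `ssim_pet`, `l1_term`, `lambda` (and `image_l1_term` when enabled).
#' @export
fusion_loss <- function(ct, pet, fused, params = NULL, lambda = 1e-4,
                        cfg = ssim_config(), image_l1_weight = 0) {
  ctv <- as_values(ct); petv <- as_values(pet); fv <- as_values(fused)
  if (!identical(dim(ctv), dim(fv)) || !identical(dim(petv), dim(fv)))
    stop("fusion_loss: image shapes differ", call. = FALSE)
  s_ct <- ssim_stat(ctv, fv, cfg)
  s_pet <- ssim_stat(petv, fv, cfg)
  l1 <- if (is.null(params)) 0 else l1_norm(params)
  img_l1 <- if (image_l1_weight > 0) mean(abs(fv - (ctv + petv) / 2)) else 0
  structure(list(total = (1 - s_ct) + (1 - s_pet) + lambda * l1 +
                   image_l1_weight * img_l1,
                 ssim_ct = s_ct, ssim_pet = s_pet,
                 l1_term = l1, lambda = lambda,
                 image_l1_term = img_l1),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> total %.6f (ssim_ct %.4f, ssim_pet %.4f, lambda*L1 %.3g)\n",
              x$total, x$ssim_ct, x$ssim_pet, x$lambda * x$l1_term))
  invisible(x)
}
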