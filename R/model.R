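#' Network architecture configuration
#'
#' Fixed architectural choices of the fusion network: a 3 x 3 convolutional
#' stem, a channel-coupling gate whose MLP bottleneck is `stem_channels /
#' mlp_reduction` wide, a spatial-pyramid coupling block pooling onto the
#' (16, 4, 2, 1) grids, a parameter-free cross-correlation fusion layer with
#' patch stride 3, and a three-stage deconvolutional decoder ending in a
#' sigmoid so fused intensities stay in \[0, 1\].
#'
#' @param stem_channels Stem feature channels (default 16).
#' @param stem_kernel Stem kernel size (3, fixed by the architecture).
#' @param mlp_reduction Bottleneck reduction ratio of the channel-coupling MLP.
#' @param spp_scales Ordered pooling grid sizes, strictly decreasing, ending at 1.
#' @param branch_channels Channels per pyramid branch (default 8).
#' @param corr_patch Correlation patch size `c(m, n)`, odd entries.
#' @param corr_stride Displacement quantum `o` of the correlation layer (3).
#' @param corr_window_radius Displacement search radius in strides; the layer
#'   emits `(2 * radius + 1)^2` response channels.
#' @param decoder_channels Output channels of the three decoder stages; the
#'   last must be 1.
#' @param decoder_kernels,decoder_strides Kernel sizes / strides of the three
#'   decoder stages (stride-1 transposed convolutions; at stride 1 with SAME
#'   padding these are realized as their equivalent stride-1 convolutions).
#' @param activation Internal nonlinearity (`"relu"`).
#' @param untied If `TRUE` the two encoder branches get independent parameter
#'   sets (ablation of the siamese weight sharing; default `FALSE`, shared).
#' @return An object of class `model_config`.
#' @export
model_config <- function(stem_channels = 16L, stem_kernel = 3L,
                         mlp_reduction = 4L, spp_scales = c(16L, 4L, 2L, 1L),
                         branch_channels = 8L,
                         corr_patch = c(3L, 3L), corr_stride = 3L,
                         corr_window_radius = 1L,
                         decoder_channels = c(16L, 8L, 1L),
                         decoder_kernels = c(3L, 3L, 3L),
                         decoder_strides = c(1L, 1L, 1L),
                         activation = "relu", untied = FALSE) {
  spp_scales <- as.integer(spp_scales)
  if (any(diff(spp_scales) >= 0) || spp_scales[length(spp_scales)] != 1L)
    stop("model_config: spp_scales must be strictly decreasing and end at 1",
         call. = FALSE)
  if (corr_stride < 1L || any(corr_patch < 1L))
    stop("model_config: corr_stride and corr_patch dims must be >= 1", call. = FALSE)
  if (any(corr_patch %% 2L == 0L))
    stop("model_config: corr_patch dims must be odd (centered patches)", call. = FALSE)
  if (length(decoder_channels) != 3L || length(decoder_kernels) != 3L ||
      length(decoder_strides) != 3L)
    stop("model_config: exactly three decoder stages are required", call. = FALSE)
  if (decoder_channels[3L] != 1L)
    stop("model_config: the final decoder stage must emit one channel", call. = FALSE)
  if (any(decoder_strides != 1L))
    stop("model_config: only stride-1 decoder stages are supported", call. = FALSE)
  if (stem_channels %% mlp_reduction != 0L)
    stop("model_config: stem_channels must be divisible by mlp_reduction", call. = FALSE)
  structure(list(stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 mlp_reduction = as.integer(mlp_reduction),
                 spp_scales = spp_scales,
                 branch_channels = as.integer(branch_channels),
                 corr_patch = as.integer(corr_patch),
                 corr_stride = as.integer(corr_stride),
                 corr_window_radius = as.integer(corr_window_radius),
                 decoder_channels = as.integer(decoder_channels),
                 decoder_kernels = as.integer(decoder_kernels),
                 decoder_strides = as.integer(decoder_strides),
                 activation = activation, untied = isTRUE(untied)),
            class = "model_config")
}

# Number of correlation response channels.
corr_channels <- function(cfg) (2L * cfg$corr_window_radius + 1L)^2L

# Encoder output channels: gated stem maps + pyramid concat + raw image.
encoder_channels <- function(cfg)
  cfg$stem_channels + length(cfg$spp_scales) * cfg$branch_channels + 1L

xavier_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Names of the encoder tensors (unprefixed).
encoder_tensor_spec <- function(cfg) {
  k <- cfg$stem_kernel
  hid <- cfg$stem_channels %/% cfg$mlp_reduction
  spec <- list(
    stem_W = list(dims = c(k, k, 1L, cfg$stem_channels),
                  fans = c(k * k, k * k * cfg$stem_channels)),
    stem_b = list(dims = cfg$stem_channels, zero = TRUE),
    cc_W1 = list(dims = c(hid, cfg$stem_channels),
                 fans = c(cfg$stem_channels, hid)),
    cc_b1 = list(dims = hid, zero = TRUE),
    cc_W2 = list(dims = c(cfg$stem_channels, hid),
                 fans = c(hid, cfg$stem_channels)),
    cc_b2 = list(dims = cfg$stem_channels, zero = TRUE),
    spp_in_W = list(dims = c(3L, 3L, cfg$stem_channels, cfg$branch_channels),
                    fans = c(9L * cfg$stem_channels, 9L * cfg$branch_channels)),
    spp_in_b = list(dims = cfg$branch_channels, zero = TRUE)
  )
  for (s in cfg$spp_scales) {
    spec[[sprintf("spp_s%d_W", s)]] <-
      list(dims = c(3L, 3L, cfg$branch_channels, cfg$branch_channels),
           fans = c(9L * cfg$branch_channels, 9L * cfg$branch_channels))
    spec[[sprintf("spp_s%d_b", s)]] <- list(dims = cfg$branch_channels, zero = TRUE)
  }
  spec
}

decoder_tensor_spec <- function(cfg) {
  cin <- c(corr_channels(cfg), cfg$decoder_channels[1:2])
  spec <- list()
  for (i in 1:3) {
    k <- cfg$decoder_kernels[i]
    spec[[sprintf("dec%d_W", i)]] <-
      list(dims = c(k, k, cin[i], cfg$decoder_channels[i]),
           fans = c(k * k * cin[i], k * k * cfg$decoder_channels[i]))
    spec[[sprintf("dec%d_b", i)]] <- list(dims = cfg$decoder_channels[i], zero = TRUE)
  }
  spec
}

#' Initialize model parameters
#'
#' Xavier/Glorot uniform initialization (variance `2 / (fan_in + fan_out)`)
#' for all weight tensors; biases start at zero. With the default tied
#' (siamese) configuration both encoder branches reference one parameter set;
#' with `untied = TRUE` the PET branch gets an independent copy drawn from
#' the same stream.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed; identical seeds give identical parameters.
#' @return An object of class `spfn_params` with elements `config` and
#'   `tensors` (named list of numeric arrays).
#' @export
init_parameters <- function(cfg = model_config(), seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  spec <- c(encoder_tensor_spec(cfg), decoder_tensor_spec(cfg))
  if (cfg$untied)
    spec <- c(spec, stats::setNames(encoder_tensor_spec(cfg),
                                    paste0("pet_", names(encoder_tensor_spec(cfg)))))
  tensors <- with_seed(seed, {
    lapply(spec, function(s) {
      if (isTRUE(s$zero)) array(0, s$dims)
      else xavier_uniform(s$dims, s$fans[1], s$fans[2])
    })
  })
  structure(list(format_version = 1L, config = cfg, tensors = tensors),
            class = "spfn_params")
}

#' @export
print.spfn_params <- function(x, ...) {
  n <- sum(vapply(x$tensors, length, integer(1)))
  cat(sprintf("<spfn_params> %d tensors, %d scalar weights%s\n",
              length(x$tensors), n,
              if (x$config$untied) " (untied encoders)" else " (siamese, shared)"))
  invisible(x)
}

# Tensor name prefix for an encoder branch ("ct" or "pet").
branch_prefix <- function(params, branch) {
  if (params$config$untied && branch == "pet") "pet_" else ""
}

check_spatial <- function(H, W, cfg) {
  s <- cfg$spp_scales[1]
  if (H %% s != 0L || W %% s != 0L)
    stop(sprintf(paste0("input spatial size %d x %d is not divisible by the ",
                        "largest pyramid scale %d; use a smaller spp_scales ",
                        "set in model_config()"), H, W, s), call. = FALSE)
  invisible(TRUE)
}

## ---- forward stages (internal, cache-carrying) ------------------------------

stem_forward <- function(x, params, branch = "ct") {
  p <- branch_prefix(params, branch); t <- params$tensors
  pre <- conv2d_same(array(x, c(dim(x), 1L)),
                     t[[paste0(p, "stem_W")]], t[[paste0(p, "stem_b")]])
  list(out = relu(pre), pre = pre, x = x)
}

cc_forward <- function(F, params, branch = "ct") {
  p <- branch_prefix(params, branch); t <- params$tensors
  C <- dim(F)[3]
  gap <- apply(F, 3L, mean)
  gmp <- apply(F, 3L, max)
  # argmax location per channel (first index on ties) for the max-pool backward
  amax <- vapply(seq_len(C), function(c) which.max(F[, , c]), integer(1))
  W1 <- t[[paste0(p, "cc_W1")]]; b1 <- t[[paste0(p, "cc_b1")]]
  W2 <- t[[paste0(p, "cc_W2")]]; b2 <- t[[paste0(p, "cc_b2")]]
  z1a <- as.vector(W1 %*% gap) + b1; ha <- relu(z1a)
  z1m <- as.vector(W1 %*% gmp) + b1; hm <- relu(z1m)
  z <- as.numeric(as.vector(W2 %*% ha) + b2 + as.vector(W2 %*% hm) + b2)
  gate <- sigmoid_(z)
  Fp <- F * rep(gate, each = dim(F)[1] * dim(F)[2])
  list(out = Fp, F = F, gap = gap, gmp = gmp, amax = amax,
       z1a = z1a, ha = ha, z1m = z1m, hm = hm, gate = gate)
}

spp_forward <- function(Fp, params, branch = "ct") {
  p <- branch_prefix(params, branch); t <- params$tensors
  cfg <- params$config
  H <- dim(Fp)[1]; W <- dim(Fp)[2]
  check_spatial(H, W, cfg)
  inner_pre <- conv2d_same(Fp, t[[paste0(p, "spp_in_W")]], t[[paste0(p, "spp_in_b")]])
  inner <- relu(inner_pre)
  B <- dim(inner)[3]
  branches <- list()
  for (s in cfg$spp_scales) {
    pooled <- array(0, c(s, s, B))
    for (c in seq_len(B)) pooled[, , c] <- block_pool(chan(inner, c), s)
    pre <- conv2d_same(pooled, t[[sprintf("%sspp_s%d_W", p, s)]],
                       t[[sprintf("%sspp_s%d_b", p, s)]])
    act <- relu(pre)
    up <- array(0, c(H, W, B))
    for (c in seq_len(B)) up[, , c] <- upsample_bilinear(chan(act, c), H, W)
    branches[[as.character(s)]] <- list(pooled = pooled, pre = pre, act = act, up = up)
  }
  Fs <- array(0, c(H, W, length(cfg$spp_scales) * B))
  for (i in seq_along(cfg$spp_scales))
    Fs[, , ((i - 1L) * B + 1L):(i * B)] <- branches[[i]]$up
  list(out = Fs, Fp = Fp, inner_pre = inner_pre, inner = inner, branches = branches)
}

encode_forward <- function(x, params, branch = "ct") {
  st <- stem_forward(x, params, branch)
  cc <- cc_forward(st$out, params, branch)
  sp <- spp_forward(cc$out, params, branch)
  H <- dim(x)[1]; W <- dim(x)[2]
  C1 <- dim(cc$out)[3]; C2 <- dim(sp$out)[3]
  out <- array(0, c(H, W, C1 + C2 + 1L))
  out[, , seq_len(C1)] <- cc$out
  out[, , C1 + seq_len(C2)] <- sp$out
  out[, , C1 + C2 + 1L] <- x
  list(out = out, stem = st, cc = cc, spp = sp, x = x)
}

# Parameter-free cross-correlation fusion. For each displacement d (a
# multiple of corr_stride within the search window) the per-pixel response is
# the channel-averaged inner product of the centered corr_patch of F1 with
# the same patch of F2 displaced by d, under SAME zero padding:
#   resp_d(i) = (1/C) * sum_p sum_c F1[c, i+p] * F2[c, i+p+d]
#             = sum_p Q_d[i+p],   Q_d = (1/C) * sum_c F1_c .* shift(F2_c, d).
corr_forward <- function(F1, F2, cfg) {
  F1 <- as_fmap(F1); F2 <- as_fmap(F2)
  if (!identical(dim(F1), dim(F2)))
    stop("cross_correlation_fuse: feature map shapes differ", call. = FALSE)
  H <- dim(F1)[1]; W <- dim(F1)[2]; C <- dim(F1)[3]
  o <- cfg$corr_stride; r <- cfg$corr_window_radius
  ph <- (cfg$corr_patch[1] - 1L) %/% 2L; pw <- (cfg$corr_patch[2] - 1L) %/% 2L
  disp <- expand.grid(dx = o * (-r:r), dy = o * (-r:r))[, c("dy", "dx")]
  D <- nrow(disp)
  out <- array(0, c(H, W, D))
  Qs <- vector("list", D)
  for (di in seq_len(D)) {
    dy <- disp$dy[di]; dx <- disp$dx[di]
    Q <- matrix(0, H, W)
    for (c in seq_len(C)) Q <- Q + chan(F1, c) * shift_mat(chan(F2, c), dy, dx)
    Q <- Q / C
    resp <- matrix(0, H, W)
    for (a in -ph:ph) for (b in -pw:pw) resp <- resp + shift_mat(Q, a, b)
    out[, , di] <- resp
    Qs[[di]] <- Q
  }
  list(out = out, F1 = F1, F2 = F2, disp = disp, ph = ph, pw = pw)
}

dec_forward <- function(Fpc, params) {
  t <- params$tensors
  pre1 <- conv2d_same(Fpc, t$dec1_W, t$dec1_b); a1 <- relu(pre1)
  pre2 <- conv2d_same(a1, t$dec2_W, t$dec2_b); a2 <- relu(pre2)
  pre3 <- conv2d_same(a2, t$dec3_W, t$dec3_b)
  fused <- sigmoid_(pre3[, , 1L])
  list(out = fused, Fpc = Fpc, pre1 = pre1, a1 = a1, pre2 = pre2, a2 = a2,
       pre3 = pre3)
}

fuse_forward <- function(ct, pet, params) {
  enc_ct <- encode_forward(ct, params, "ct")
  enc_pet <- encode_forward(pet, params, "pet")
  corr <- corr_forward(enc_ct$out, enc_pet$out, params$config)
  dec <- dec_forward(corr$out, params)
  list(fused = dec$out, enc_ct = enc_ct, enc_pet = enc_pet, corr = corr,
       dec = dec)
}

## ---- public stage API -------------------------------------------------------

#' Convolutional stem
#'
#' Extracts `stem_channels` low-level feature maps from a normalized image
#' with 3 x 3 kernels, SAME padding and ReLU activation. This is the feature
#' block the two coupling modules operate on.
#'
#' @param img A normalized `image2d`.
#' @param params An `spfn_params` object.
#' @param branch `"ct"` or `"pet"` (only relevant for untied encoders).
#' @return A feature map array `H x W x stem_channels`.
#' @export
conv_stem <- function(img, params, branch = "ct") {
  stopifnot(inherits(params, "spfn_params"))
  if (inherits(img, "image2d") && !img$normalized)
    stop("conv_stem: input image must be normalized", call. = FALSE)
  stem_forward(as_values(img), params, branch)$out
}

#' Channel coupling (channel attention) gate
#'
#' Computes per-channel gates `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`
#' with one MLP shared between the two pooling branches, and rescales each
#' channel of `F` by its gate. Gates lie strictly in (0, 1); with all-zero
#' MLP weights every gate is 0.5.
#'
#' @param F Feature map array from [conv_stem()].
#' @param params An `spfn_params` object.
#' @param branch `"ct"` or `"pet"`.
#' @return Gated feature map, same shape as `F`, with the gate vector
#'   attached as attribute `"gate"`.
#' @export
channel_coupling <- function(F, params, branch = "ct") {
  stopifnot(inherits(params, "spfn_params"))
  cc <- cc_forward(as_fmap(F), params, branch)
  structure(cc$out, gate = cc$gate)
}

#' Spatial pyramid coupling
#'
#' An inner 3 x 3 convolution, adaptive average pooling onto the pyramid
#' grids (default 16, 4, 2, 1), a per-scale 3 x 3 convolution, bilinear
#' upsampling of every branch back to the input resolution, and channel
#' concatenation of the branches.
#'
#' @param F Gated feature map from [channel_coupling()].
#' @inheritParams channel_coupling
#' @return Feature map with `length(spp_scales) * branch_channels` channels.
#' @export
spatial_pyramid_coupling <- function(F, params, branch = "ct") {
  stopifnot(inherits(params, "spfn_params"))
  spp_forward(as_fmap(F), params, branch)$out
}

#' Encode one modality
#'
#' Runs stem, channel coupling and spatial pyramid coupling, then superimposes
#' (channel-concatenates) the gated stem features, the pyramid features and
#' the original image into the branch output. Both modalities run through
#' this one operation; with tied (siamese) parameters identical inputs give
#' bitwise-identical encodings on either branch.
#'
#' @param img A normalized `image2d`.
#' @inheritParams channel_coupling
#' @return Feature map with `stem_channels + 4 * branch_channels + 1` channels
#'   at the default wiring.
#' @export
encode <- function(img, params, branch = "ct") {
  stopifnot(inherits(params, "spfn_params"))
  if (inherits(img, "image2d") && !img$normalized)
    stop("encode: input image must be normalized", call. = FALSE)
  encode_forward(as_values(img), params, branch)$out
}

#' Cross-correlation fusion layer
#'
#' Parameter-free fusion of the two encoder outputs: at each spatial location
#' the centered `corr_patch` of the CT features is inner-producted with the
#' PET-feature patch displaced by each displacement in a
#' `(2r + 1) x (2r + 1)` window of multiples of the patch stride `o = 3`,
#' giving one response channel per displacement (channel-averaged, SAME zero
#' padding, output spatial size = input size).
#'
#' @param F_ct,F_pet Same-shape feature maps from [encode()].
#' @param cfg A [model_config()] supplying patch size, stride and radius.
#' @return Response array `H x W x (2r + 1)^2`; displacement channels are
#'   ordered row-major over (dy, dx).
#' @export
cross_correlation_fuse <- function(F_ct, F_pet, cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  corr_forward(F_ct, F_pet, cfg)$out
}

#' Decode fused features to an image
#'
#' Three stride-1 deconvolutional stages (ReLU, ReLU, sigmoid); the sigmoid
#' output stage bounds fused intensities to \[0, 1\] and the SAME padding
#' keeps the source-image spatial size.
#'
#' @param F_pc Fused feature map from [cross_correlation_fuse()].
#' @param params An `spfn_params` object.
#' @return An `image2d` with modality `"FUSED"`.
#' @export
decode <- function(F_pc, params) {
  stopifnot(inherits(params, "spfn_params"))
  image2d(dec_forward(as_fmap(F_pc), params)$out, modality = "FUSED",
          normalized = TRUE)
}

#' Fuse a registered PET/CT pair
#'
#' The full forward pass: both images through the shared encoder, the
#' cross-correlation fusion layer, and the decoder. Deterministic given the
#' parameters.
#'
#' @param pair An `image_pair`.
#' @param params An `spfn_params` object.
#' @return An `image2d` with modality `"FUSED"`, same size as the sources.
#' @export
fuse <- function(pair, params) {
  stopifnot(inherits(pair, "image_pair"), inherits(params, "spfn_params"))
  fw <- fuse_forward(pair$ct$values, pair$pet$values, params)
  image2d(fw$fused, modality = "FUSED", normalized = TRUE)
}

#' Save / load a model checkpoint
#'
#' A single-file archive of the named parameter tensors together with the
#' architecture configuration and a format version; `load_checkpoint()`
#' restores it bitwise, so save/load/fuse reproduces outputs exactly.
#'
#' @param params An `spfn_params` object.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` the
#'   restored `spfn_params`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "spfn_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  params <- readRDS(path)
  if (!inherits(params, "spfn_params") || is.null(params$format_version))
    stop(sprintf("load_checkpoint: '%s' is not a model checkpoint", path),
         call. = FALSE)
  params
}
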