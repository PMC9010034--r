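#' Histogram configuration for entropy-based metrics
#'
#' Intensity binning used by [entropy()] and [nmi()]: 256 uniform bins on
#' \[0, 1\] with natural-log entropies. Values at the upper range edge fall in
#' the last bin.
#'
#' @param n_bins Number of bins (>= 2).
#' @param range Intensity range covered by the bins.
#' @return An object of class `histogram_config`.
#' @export
histogram_config <- function(n_bins = 256L, range = c(0, 1)) {
  if (n_bins < 2L) stop("histogram_config: n_bins must be >= 2", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), range = range),
            class = "histogram_config")
}

bin_index <- function(v, cfg) {
  idx <- floor((v - cfg$range[1]) / diff(cfg$range) * cfg$n_bins) + 1L
  pmin(pmax(idx, 1L), cfg$n_bins)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Mean intensity
#'
#' Arithmetic mean of all pixels; reflects overall image brightness.
#'
#' @param img An `image2d` or numeric matrix.
#' @return Scalar mean.
#' @export
mean_value <- function(img) mean(as_values(img))

#' Standard deviation of intensity
#'
#' Population standard deviation (divide by the pixel count, not n - 1);
#' reflects image contrast.
#'
#' @inheritParams mean_value
#' @return Scalar standard deviation (>= 0).
#' @export
std_value <- function(img) {
  v <- as_values(img)
  sqrt(mean((v - mean(v))^2))
}

#' Average gradient
#'
#' Mean over the interior grid of `sqrt((dI/dx^2 + dI/dy^2) / 2)` with
#' forward-difference gradients (the last row and column carry no forward
#' difference and are excluded from the mean); a proxy for sharpness and
#' texture.
#'
#' @inheritParams mean_value
#' @return Scalar average gradient (>= 0).
#' @export
average_gradient <- function(img) {
  v <- as_values(img)
  m <- nrow(v); n <- ncol(v)
  if (m < 2L || n < 2L)
    stop("average_gradient: image must be at least 2 x 2", call. = FALSE)
  dx <- v[1:(m - 1), 2:n] - v[1:(m - 1), 1:(n - 1)]
  dy <- v[2:m, 1:(n - 1)] - v[1:(m - 1), 1:(n - 1)]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Shannon entropy of the intensity histogram
#'
#' `-sum(p * ln(p))` over the binned intensity distribution; empty bins
#' contribute zero. A constant image has entropy 0; uniform occupancy of all
#' 256 default bins gives `ln(256)`.
#'
#' @inheritParams mean_value
#' @param cfg A [histogram_config()].
#' @return Scalar entropy in nats (>= 0).
#' @export
entropy <- function(img, cfg = histogram_config()) {
  v <- as_values(img)
  entropy_from_counts(tabulate(bin_index(v, cfg), nbins = cfg$n_bins))
}

#' Root mean square error between two images
#'
#' @param x,y Same-shape images.
#' @return Scalar RMSE (>= 0).
#' @export
rmse <- function(x, y) {
  xv <- as_values(x); yv <- as_values(y)
  if (!identical(dim(xv), dim(yv)))
    stop("rmse: image shapes differ", call. = FALSE)
  sqrt(mean((xv - yv)^2))
}

#' Normalized mutual information of a fused image with its two sources
#'
#' `2 * [H(I1, F) / (H(I1) + H(F)) + H(I2, F) / (H(I2) + H(F))]` with binned
#' marginal and joint entropies (natural log). Because a joint entropy is
#' bounded by `max(H1, H2) <= H12 <= H1 + H2`, each ratio lies in
#' \[1/2, 1\] and the statistic in \[2, 4\]: 2 when the fused image is a
#' deterministic copy of both sources, approaching 4 for independent images.
#' Degenerate all-constant marginals (zero entropy) take the lower-bound
#' ratio 1/2.
#'
#' @param i1,i2,fused Same-shape images.
#' @param cfg A [histogram_config()].
#' @return Scalar in \[2, 4\].
#' @export
nmi <- function(i1, i2, fused, cfg = histogram_config()) {
  v1 <- as_values(i1); v2 <- as_values(i2); vf <- as_values(fused)
  if (!identical(dim(v1), dim(vf)) || !identical(dim(v2), dim(vf)))
    stop("nmi: image shapes differ", call. = FALSE)
  bf <- bin_index(vf, cfg)
  Hf <- entropy_from_counts(tabulate(bf, nbins = cfg$n_bins))
  ratio <- function(v) {
    b <- bin_index(v, cfg)
    H <- entropy_from_counts(tabulate(b, nbins = cfg$n_bins))
    joint <- entropy_from_counts(
      tabulate((b - 1L) * cfg$n_bins + bf, nbins = cfg$n_bins^2))
    if (H + Hf <= 0) 0.5 else joint / (H + Hf)
  }
  2 * (ratio(v1) + ratio(v2))
}

#' Pixel-domain visual information fidelity
#'
#' The scalar Gaussian-scale-mixture VIF: at four dyadic scales, local
#' Gaussian-window statistics yield a per-block gain `g` and residual
#' variance, and the metric is the ratio of the information the "human eye"
#' channel (additive Gaussian noise, variance `sigma_nsq = 2`) extracts from
#' the distorted versus the reference image. Equals 1 when the images are
#' identical and tends to 0 under total information loss.
#'
#' @param reference,distorted Same-shape images; must be large enough for the
#'   coarsest scale's window.
#' @param sigma_nsq Visual-noise variance (default 2).
#' @param scales Number of dyadic scales (default 4).
#' @return Scalar VIF (>= 0; 1 at identity).
#' @export
vif <- function(reference, distorted, sigma_nsq = 2, scales = 4L) {
  ref <- as_values(reference); dist <- as_values(distorted)
  if (!identical(dim(ref), dim(dist)))
    stop("vif: image shapes differ", call. = FALSE)
  eps <- 1e-10
  num <- 0; den <- 0
  for (scale in seq_len(scales)) {
    N <- 2^(scales - scale + 1) + 1
    win <- gauss_window2d(N, N / 5)
    if (scale > 1) {
      if (nrow(ref) < N || ncol(ref) < N)
        stop("vif: image smaller than the coarsest scale", call. = FALSE)
      ref <- filter2_valid(ref, win)
      dist <- filter2_valid(dist, win)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    if (nrow(ref) < N || ncol(ref) < N)
      stop("vif: image smaller than the coarsest scale", call. = FALSE)
    mu1 <- filter2_valid(ref, win); mu2 <- filter2_valid(dist, win)
    s1 <- filter2_valid(ref * ref, win) - mu1^2
    s2 <- filter2_valid(dist * dist, win) - mu2^2
    s12 <- filter2_valid(ref * dist, win) - mu1 * mu2
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
  if (den <= eps) return(NA_real_)
  num / den
}

#' Evaluate a fused image against its source pair
#'
#' The seven-statistic quality report: brightness (mean), contrast (std),
#' sharpness (average gradient) and entropy of the fused image alone, plus
#' the referenced statistics against both sources — RMSE and VIF averaged
#' over the CT and PET references, and the normalized mutual information of
#' the fused image with both.
#'
#' @param pair An `image_pair`.
#' @param fused The fused `image2d` for this pair.
#' @param hist_cfg A [histogram_config()].
#' @return An object of class `metric_report`: a named list with fields
#'   `id, mean, std, ag, ent, rmse, nmi, vif` plus per-source components
#'   `rmse_ct, rmse_pet, vif_ct, vif_pet`.
#' @export
evaluate_pair <- function(pair, fused, hist_cfg = histogram_config()) {
  stopifnot(inherits(pair, "image_pair"))
  fv <- as_values(fused)
  r_ct <- rmse(pair$ct, fv); r_pet <- rmse(pair$pet, fv)
  v_ct <- vif(pair$ct, fv); v_pet <- vif(pair$pet, fv)
  structure(list(id = pair$id,
                 mean = mean_value(fv), std = std_value(fv),
                 ag = average_gradient(fv), ent = entropy(fv, hist_cfg),
                 rmse = (r_ct + r_pet) / 2,
                 nmi = nmi(pair$ct, pair$pet, fv, hist_cfg),
                 vif = (v_ct + v_pet) / 2,
                 rmse_ct = r_ct, rmse_pet = r_pet,
                 vif_ct = v_ct, vif_pet = v_pet),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> '%s' mean %.4f std %.4f ag %.4f ent %.4f ",
                     "rmse %.4f nmi %.3f vif %.4f\n"),
              x$id, x$mean, x$std, x$ag, x$ent, x$rmse, x$nmi, x$vif))
  invisible(x)
}

report_columns <- c("id", "mean", "std", "ag", "ent", "rmse", "nmi", "vif")

#' Write / read metric reports as CSV
#'
#' Columns are exactly `id, mean, std, ag, ent, rmse, nmi, vif`; values are
#' written at full precision so a round-trip reproduces them.
#'
#' @param reports A `metric_report` or list of them.
#' @param path CSV file path.
#' @return `write_metric_reports()` the path invisibly;
#'   `read_metric_reports()` a data.frame with the report columns.
#' @export
write_metric_reports <- function(reports, path) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id, mean = r$mean, std = r$std, ag = r$ag, ent = r$ent,
               rmse = r$rmse, nmi = r$nmi, vif = r$vif)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(report_columns, collapse = ","), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(c(df$id[i], sprintf("%.17g", as.numeric(df[i, -1]))),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_metric_reports
#' @export
read_metric_reports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df), report_columns))
  df
}
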