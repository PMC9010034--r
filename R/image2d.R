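#' Single-channel 2-D image
#'
#' The package's basic raster container: a numeric matrix of intensities plus a
#' modality tag and a flag recording whether the image has been min-max
#' normalized to \[0, 1\]. Rows index image height (origin top-left), columns
#' index width; this row-major, pixel-center convention is used by every
#' resampling and pooling operation in the package.
#'
#' @param values Numeric matrix (height x width), all finite.
#' @param modality One of `"CT"`, `"PET"`, `"FUSED"`, `"OTHER"`.
#' @param normalized Logical; `TRUE` asserts all values lie in \[0, 1\].
#' @return An object of class `image2d`.
#' @export
image2d <- function(values, modality = c("OTHER", "CT", "PET", "FUSED"),
                    normalized = FALSE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("image2d: `values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image2d: dimensions must be >= 1 x 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("image2d: all values must be finite", call. = FALSE)
  if (normalized && (min(values) < 0 || max(values) > 1))
    stop("image2d: normalized images must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, modality = modality, normalized = normalized),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %s %d x %d, range [%.4g, %.4g]%s\n",
              x$modality, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$values)

# Accept either an image2d or a bare matrix; return the matrix.
as_values <- function(img) {
  if (inherits(img, "image2d")) img$values
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected an image2d or a numeric matrix", call. = FALSE)
}

#' Registered CT/PET image pair
#'
#' A same-resolution, normalized (CT, PET) pair: the unit of training and
#' fusion. Construct with [make_pair()], which resamples and normalizes.
#'
#' @param ct,pet `image2d` objects with identical dimensions, both normalized.
#' @param id Identifier string.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(ct, pet, id = "pair") {
  stopifnot(inherits(ct, "image2d"), inherits(pet, "image2d"))
  if (!identical(dim(ct$values), dim(pet$values)))
    stop("image_pair: ct and pet dimensions differ", call. = FALSE)
  if (!ct$normalized || !pet$normalized)
    stop("image_pair: both images must be normalized", call. = FALSE)
  structure(list(ct = ct, pet = pet, id = as.character(id)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> '%s' %d x %d\n", x$id,
              nrow(x$ct$values), ncol(x$ct$values)))
  invisible(x)
}

#' Min-max normalize an image
#'
#' Affine rescaling `(v - min) / (max - min)` so the output spans exactly
#' \[0, 1\]. A constant image maps to all zeros (documented degenerate rule:
#' avoids division by zero). Idempotent on images already spanning \[0, 1\].
#'
#' @param img An `image2d` or numeric matrix.
#' @return A normalized `image2d` (modality preserved when given an `image2d`).
#' @export
minmax_normalize <- function(img) {
  v <- as_values(img)
  rng <- range(v)
  out <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
         else array(0, dim(v))
  modality <- if (inherits(img, "image2d")) img$modality else "OTHER"
  image2d(out, modality = modality, normalized = TRUE)
}

#' Resample an image to a target size
#'
#' Separable bilinear (default) or bicubic (Catmull-Rom) interpolation with
#' pixel-center alignment: output pixel center j (0-based) samples input
#' coordinate `(j + 0.5) * w_in / w_out - 0.5`, clamped at the borders.
#' Constant images map to the same constant, and bilinear output values stay
#' within the input range envelope.
#'
#' @param img An `image2d` or numeric matrix.
#' @param height,width Target dimensions (>= 1).
#' @param method `"bilinear"` or `"bicubic"`.
#' @return Resampled `image2d`.
#' @export
resample_to <- function(img, height, width, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  if (height < 1L || width < 1L) stop("resample_to: targets must be >= 1", call. = FALSE)
  v <- as_values(img)
  out <- interp_matrix(nrow(v), height, method) %*% v %*%
    t(interp_matrix(ncol(v), width, method))
  modality <- if (inherits(img, "image2d")) img$modality else "OTHER"
  normalized <- if (inherits(img, "image2d")) img$normalized else FALSE
  if (normalized) out <- pmin(pmax(out, 0), 1)  # bicubic can overshoot
  image2d(out, modality = modality, normalized = normalized)
}

# n_out x n_in sparse-structure interpolation matrix, pixel-center aligned.
interp_matrix <- function(n_in, n_out, method = "bilinear") {
  M <- matrix(0, n_out, n_in)
  x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  if (method == "bilinear") {
    x <- pmin(pmax(x, 0), n_in - 1)
    i0 <- pmin(floor(x), n_in - 1)
    t <- x - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    for (j in seq_len(n_out)) {
      M[j, i0[j] + 1] <- M[j, i0[j] + 1] + (1 - t[j])
      M[j, i1[j] + 1] <- M[j, i1[j] + 1] + t[j]
    }
  } else {  # Catmull-Rom cubic, border clamped
    for (j in seq_len(n_out)) {
      xc <- x[j]
      i1 <- floor(xc)
      t <- xc - i1
      idx <- pmin(pmax(i1 + (-1:2), 0), n_in - 1) + 1
      w <- c(-0.5 * t^3 + t^2 - 0.5 * t,
             1.5 * t^3 - 2.5 * t^2 + 1,
             -1.5 * t^3 + 2 * t^2 + 0.5 * t,
             0.5 * t^3 - 0.5 * t^2)
      for (k in 1:4) M[j, idx[k]] <- M[j, idx[k]] + w[k]
    }
  }
  M
}

#' Assemble a registered, normalized CT/PET pair
#'
#' Resamples the PET image to the CT's resolution (the modalities differ
#' natively: CT 512 x 512 vs PET 128 x 128), min-max normalizes both per
#' image (the two carry physically different units, HU vs tracer uptake),
#' and returns an [image_pair()]. Registration is assumed done upstream;
#' this function never deforms images.
#'
#' @param ct,pet `image2d` objects (or matrices) of the same registered slice.
#' @param id Identifier string.
#' @param method Interpolation method passed to [resample_to()].
#' @return An `image_pair` at the CT resolution.
#' @export
make_pair <- function(ct, pet, id = "pair", method = "bilinear") {
  ctv <- as_values(ct); petv <- as_values(pet)
  ct_img <- image2d(ctv, "CT")
  pet_img <- image2d(petv, "PET")
  pet_rs <- resample_to(pet_img, nrow(ctv), ncol(ctv), method = method)
  ct_n <- minmax_normalize(ct_img)
  pet_n <- minmax_normalize(pet_rs)
  if (!identical(dim(ct_n$values), dim(pet_n$values)))
    stop("make_pair: internal dimension mismatch after resampling", call. = FALSE)
  image_pair(ct_n, pet_n, id = id)
}
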