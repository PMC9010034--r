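#' Configuration for the synthetic thorax phantom generator
#'
#' The generator emulates the statistical structure of registered PET/CT lung
#' slices: a CT-like channel with sharp anatomy (body outline, two dark lung
#' fields, bright spine and rib band, fine Gaussian texture) and a
#' co-registered PET-like channel that is a heavily smoothed, natively
#' low-resolution image with high-intensity lesion hotspots inside the lungs.
#'
#' @param ct_size CT pixels per side (default 128 for desk scale; 512 matches
#'   clinical CT resolution).
#' @param pet_native_size Native PET pixels per side; must divide `ct_size`
#'   (default `ct_size / 4`, mirroring the clinical 512 vs 128 ratio).
#' @param n_hotspots Number of lesion hotspots (>= 0).
#' @param hotspot_radius_range Hotspot radius range in CT pixels.
#' @param hotspot_peak_range Hotspot peak intensity range, in (0, 1].
#' @param pet_blur_sigma PET smoothing kernel width in CT pixels.
#' @param ct_noise_sigma CT additive texture noise sd, relative intensity.
#' @param seed Integer seed; the full dataset is a deterministic function of it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(ct_size = 128L, pet_native_size = ct_size %/% 4L,
                           n_hotspots = 2L,
                           hotspot_radius_range = pmax(c(3, 8) * ct_size / 128, 1),
                           hotspot_peak_range = c(0.6, 0.95),
                           pet_blur_sigma = 2 * ct_size / 128,
                           ct_noise_sigma = 0.02,
                           seed = 0L) {
  ct_size <- as.integer(ct_size); pet_native_size <- as.integer(pet_native_size)
  if (ct_size < 8L || pet_native_size < 1L || ct_size %% pet_native_size != 0L)
    stop("phantom_config: ct_size must be a positive multiple of pet_native_size",
         call. = FALSE)
  if (n_hotspots < 0L) stop("phantom_config: n_hotspots must be >= 0", call. = FALSE)
  if (any(hotspot_peak_range <= 0) || any(hotspot_peak_range > 1) ||
      ct_noise_sigma < 0 || ct_noise_sigma > 1)
    stop("phantom_config: intensity parameters must lie in [0, 1]", call. = FALSE)
  if (diff(hotspot_radius_range) < 0 || hotspot_radius_range[1] < 1)
    stop("phantom_config: invalid hotspot_radius_range", call. = FALSE)
  structure(list(ct_size = ct_size, pet_native_size = pet_native_size,
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_radius_range = hotspot_radius_range,
                 hotspot_peak_range = hotspot_peak_range,
                 pet_blur_sigma = pet_blur_sigma,
                 ct_noise_sigma = ct_noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Jittered parametric anatomy shared by the CT and PET renderers: a fixed
# ellipse layout with seeded +/-10% jitter on centers and axes. Coordinates
# are normalized to [0, 1] x [0, 1], origin top-left, rows = y.
phantom_geometry <- function(cfg) {
  with_seed(cfg$seed * 3L + 1L, {
    j <- function(x) x * runif(length(x), 0.9, 1.1)
    list(
      body  = list(c = c(0.50, 0.50) * runif(2, 0.97, 1.03), a = j(c(0.36, 0.44))),
      lungL = list(c = c(0.48, 0.31) * runif(2, 0.95, 1.05), a = j(c(0.22, 0.13))),
      lungR = list(c = c(0.48, 0.69) * runif(2, 0.95, 1.05), a = j(c(0.22, 0.13))),
      spine = list(c = c(0.78, 0.50) * runif(2, 0.98, 1.02), a = j(c(0.07, 0.05)))
    )
  })
}

# Squared normalized ellipse distance field: <= 1 inside.
ellipse_field <- function(n, e) {
  y <- (seq_len(n) - 0.5) / n
  x <- (seq_len(n) - 0.5) / n
  outer(((y - e$c[1]) / e$a[1])^2, ((x - e$c[2]) / e$a[2])^2, `+`)
}

#' Generate a CT-like phantom slice
#'
#' Piecewise-constant anatomy (air 0, soft tissue 0.5, lung fields 0.12, rib
#' band 0.8, spine 0.95) plus additive Gaussian texture at `ct_noise_sigma`,
#' clipped to \[0, 1\]. Deterministic given `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @return An `image2d` with modality `"CT"`, values in \[0, 1\].
#' @export
generate_ct_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$ct_size
  g <- phantom_geometry(cfg)
  body <- ellipse_field(n, g$body)
  img <- matrix(0, n, n)
  img[body <= 1] <- 0.5
  img[body <= 1 & body >= 0.88] <- 0.8          # rib band along the body shell
  img[ellipse_field(n, g$lungL) <= 1] <- 0.12
  img[ellipse_field(n, g$lungR) <= 1] <- 0.12
  img[ellipse_field(n, g$spine) <= 1] <- 0.95
  if (cfg$ct_noise_sigma > 0)
    img <- img + with_seed(cfg$seed * 3L + 2L,
                           matrix(stats::rnorm(n * n, 0, cfg$ct_noise_sigma), n, n))
  image2d(pmin(pmax(img, 0), 1), modality = "CT", normalized = TRUE)
}

#' Generate the PET-like channel registered to a CT phantom
#'
#' Draws `n_hotspots` disjoint lesion disks inside the lung fields, renders
#' them as isotropic Gaussian-profile blobs (peaks in `hotspot_peak_range`) on
#' a low smooth background, Gaussian-blurs with `pet_blur_sigma`, and block-
#' averages down to the native PET resolution. The full-resolution lesion
#' support mask is returned alongside so downstream stages can be tested
#' against known lesion geometry.
#'
#' @param ct The CT phantom generated from the same `cfg` (geometry is shared).
#' @param cfg A [phantom_config()].
#' @return `list(pet, lesion_mask)`: `pet` an `image2d` (modality `"PET"`) at
#'   `pet_native_size`, `lesion_mask` a logical `ct_size` x `ct_size` matrix.
#' @export
generate_pet_phantom <- function(ct, cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$ct_size
  if (!identical(dim(as_values(ct)), c(n, n)))
    stop("generate_pet_phantom: ct was not generated at cfg$ct_size", call. = FALSE)
  g <- phantom_geometry(cfg)
  lungs <- pmin(ellipse_field(n, g$lungL), ellipse_field(n, g$lungR))
  body <- ellipse_field(n, g$body)

  spots <- with_seed(cfg$seed * 3L + 3L, {
    centers <- matrix(0, 0, 2)
    radii <- numeric(0); peaks <- numeric(0)
    # candidate centers: comfortably interior lung pixels
    cand <- which(lungs <= 0.55, arr.ind = TRUE)
    if (cfg$n_hotspots > 0L && nrow(cand) == 0L)
      stop("generate_pet_phantom: lung fields too small to place hotspots",
           call. = FALSE)
    for (k in seq_len(cfg$n_hotspots)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        r <- stats::runif(1, cfg$hotspot_radius_range[1], cfg$hotspot_radius_range[2])
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        ok <- TRUE
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
          ok <- all(d > radii + r + 2)   # keep lesion disks disjoint
        }
        if (ok) {
          centers <- rbind(centers, ctr)
          radii <- c(radii, r)
          peaks <- c(peaks, stats::runif(1, cfg$hotspot_peak_range[1],
                                         cfg$hotspot_peak_range[2]))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("generate_pet_phantom: could not place disjoint hotspots in the lung fields",
             call. = FALSE)
    }
    list(centers = centers, radii = radii, peaks = peaks)
  })

  # low, smooth physiological background: mild body uptake, quiet lungs
  pet <- matrix(0.03, n, n)
  pet[body <= 1] <- 0.12
  pet[lungs <= 1] <- 0.06
  mask <- matrix(FALSE, n, n)
  if (length(spots$radii) > 0) {
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    for (k in seq_along(spots$radii)) {
      d2 <- (rows - spots$centers[k, 1])^2 + (cols - spots$centers[k, 2])^2
      r <- spots$radii[k]
      pet <- pet + spots$peaks[k] * exp(-d2 / (2 * (r / 2)^2))
      mask <- mask | (d2 <= r^2)
    }
  }
  pet <- gauss_blur(pet, cfg$pet_blur_sigma)
  f <- n %/% cfg$pet_native_size
  pet_native <- block_pool(pet, cfg$pet_native_size)
  pet_native <- pmin(pmax(pet_native, 0), 1)
  list(pet = image2d(pet_native, modality = "PET", normalized = TRUE),
       lesion_mask = mask)
}

#' Generate a dataset of registered phantom pairs
#'
#' Per-pair seeds are derived deterministically from `cfg$seed`, so the whole
#' dataset is a pure function of the configuration.
#'
#' @param n Number of pairs (>= 1).
#' @param cfg A [phantom_config()]; `cfg$seed` seeds the whole dataset.
#' @return A list of `phantom_pair` objects, each with elements `ct`
#'   (`image2d`), `pet_native` (`image2d`), `lesion_mask`, `seed_used`, `id`.
#' @export
generate_dataset <- function(n, cfg) {
  stopifnot(inherits(cfg, "phantom_config"), n >= 1)
  lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed + i * 9973L) %% 2147483647L)
    ct <- generate_ct_phantom(cfg_i)
    pp <- generate_pet_phantom(ct, cfg_i)
    structure(list(ct = ct, pet_native = pp$pet, lesion_mask = pp$lesion_mask,
                   seed_used = cfg_i$seed, id = sprintf("phantom-%04d", i)),
              class = "phantom_pair")
  })
}

#' Convert a phantom pair to a training-ready image pair
#'
#' Upsamples the native-resolution PET back to the CT grid and normalizes both
#' channels via [make_pair()].
#'
#' @param pp A `phantom_pair` from [generate_dataset()].
#' @param method Interpolation method for the PET upsampling.
#' @return An `image_pair`.
#' @export
phantom_to_pair <- function(pp, method = "bilinear") {
  stopifnot(inherits(pp, "phantom_pair"))
  make_pair(pp$ct, pp$pet_native, id = pp$id, method = method)
}
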