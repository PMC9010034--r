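#' Load a single-slice image from disk
#'
#' Reads PNG (8/16-bit, values rescaled back to stored integer range), TIFF,
#' single-slice NIfTI, or the package's plain-text float archive (see
#' [write_image_archive()]). Values are returned in native units (e.g.
#' Hounsfield units for CT NIfTI) with the `normalized` flag `FALSE`;
#' normalization is an explicit, separate step ([minmax_normalize()]).
#'
#' DICOM is not supported by this build; single-slice DICOM exports should be
#' converted to NIfTI or 16-bit PNG upstream.
#'
#' @param path File path.
#' @param format Optional hint: `"png"`, `"tiff"`, `"nifti"`, `"archive"`;
#'   inferred from the file extension when omitted.
#' @param modality Modality tag for the returned image.
#' @return An `image2d`, `normalized = FALSE`.
#' @export
load_image <- function(path, format = NULL, modality = "OTHER") {
  if (!file.exists(path))
    stop(sprintf("load_image: file not found: '%s'", path), call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff",
      nii = "nifti", gz = "nifti",
      dcm = "dicom", dicom = "dicom",
      "archive")
  }
  v <- switch(format,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]       # grayscale from first channel
      # readPNG returns [0,1]; restore stored integer scale (8- vs 16-bit)
      scale <- if (max(abs(a * 255 - round(a * 255))) < 1e-6) 255 else 65535
      round(a * scale)
    },
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("load_image: the 'tiff' package is required for TIFF input", call. = FALSE)
      a <- tiff::readTIFF(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      a
    },
    nifti = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("load_image: the 'RNifti' package is required for NIfTI input", call. = FALSE)
      a <- as.array(RNifti::readNifti(path))
      d <- dim(a)
      if (length(d) > 2L) {
        if (prod(d[-(1:2)]) != 1L)
          stop(sprintf("load_image: '%s' is a volume, not a single slice", path),
               call. = FALSE)
        a <- array(a, d[1:2])
      }
      # NIfTI stores x (width) first; present as a plain height x width matrix
      a <- t(a)
      matrix(as.numeric(a), nrow(a), ncol(a))
    },
    dicom = stop(sprintf(
      "load_image: DICOM is not supported ('%s'); convert to NIfTI or 16-bit PNG",
      path), call. = FALSE),
    archive = read_image_archive(path)$values,
    stop(sprintf("load_image: unknown format '%s' for '%s'", format, path),
         call. = FALSE)
  )
  if (!is.matrix(v)) v <- as.matrix(v)
  image2d(v, modality = modality, normalized = FALSE)
}

#' Write / read the lossless plain-text image archive
#'
#' A small text format for exact floating-point round-trips of fixtures and
#' fused outputs: a two-line header (`spfn-image 1`, then
#' `<height> <width> <modality> <normalized>`) followed by one row of
#' `%.17g`-formatted values per image row. `%.17g` round-trips IEEE doubles
#' bitwise.
#'
#' @param img An `image2d`.
#' @param path Destination / source file path.
#' @return `write_image_archive()` returns `path` invisibly;
#'   `read_image_archive()` returns an `image2d`.
#' @export
write_image_archive <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  v <- img$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("spfn-image 1", con)
  writeLines(sprintf("%d %d %s %d", nrow(v), ncol(v), img$modality,
                     as.integer(img$normalized)), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_image_archive
#' @export
read_image_archive <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "spfn-image"))
    stop(sprintf("read_image_archive: '%s' is not an spfn image archive", path),
         call. = FALSE)
  hdr <- strsplit(lines[2L], " ", fixed = TRUE)[[1L]]
  h <- as.integer(hdr[1L]); w <- as.integer(hdr[2L])
  v <- matrix(0, h, w)
  for (i in seq_len(h))
    v[i, ] <- as.numeric(strsplit(lines[2L + i], " ", fixed = TRUE)[[1L]])
  image2d(v, modality = hdr[3L], normalized = hdr[4L] == "1")
}

#' Write an image as 8-bit PNG
#'
#' Intensities are clipped to \[0, 1\] and quantized to 255 levels; use
#' [write_image_archive()] alongside when lossless values are needed.
#'
#' @param img An `image2d` or numeric matrix.
#' @param path Destination path.
#' @export
write_png <- function(img, path) {
  v <- pmin(pmax(as_values(img), 0), 1)
  png::writePNG(v, path)
  invisible(path)
}
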