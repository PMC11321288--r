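# Input standardization and score conversion. Coordinate convention
# throughout the package: row 1 is the top of the scan (vitreous), sizes
# are (height, width), pixel sizes are (axial, mediolateral) micrometres.

#' Standardize a raw B-scan
#'
#' Bilinear resample to the target size followed by per-image min-max
#' intensity scaling to `[0, 1]`. The full-scale standard is 208 x 256
#' pixels at 7.0 x 23.4 um per pixel.
#'
#' @param image grayscale numeric matrix (color arrays are rejected).
#' @param target_hw output size `c(height, width)`.
#' @param pixel_size input pixel size `c(axial, mediolateral)` in um;
#'   required metadata unless `allow_unknown_pixel_size`.
#' @param target_pixel_size pixel size recorded on the output.
#' @param allow_unknown_pixel_size permit images without pixel-size
#'   metadata.
#' @return a `"bscan"` matrix in `[0, 1]` with pixel-size metadata. A
#'   constant input maps to all zeros with a warning.
#' @export
standardize_bscan <- function(image, target_hw = c(208L, 256L),
                              pixel_size = NULL,
                              target_pixel_size = c(7.0, 23.4),
                              allow_unknown_pixel_size = FALSE) {
  if (is.array(image) && length(dim(image)) == 3) {
    stop("color input rejected: expected a single-channel grayscale matrix")
  }
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(pixel_size) && !allow_unknown_pixel_size) {
    stop("unknown input pixel size; pass pixel_size or allow_unknown_pixel_size = TRUE")
  }
  H <- nrow(image); W <- ncol(image)
  Ho <- as.integer(target_hw[1]); Wo <- as.integer(target_hw[2])
  A <- cbind(H / Ho, 0, 0, W / Wo, (H + 1) / 2, (W + 1) / 2)
  out <- matrix(nn_warp(matrix(as.vector(image), ncol = 1), H, W, A, Ho, Wo),
                Ho, Wo)
  rng <- range(out)
  if (diff(rng) < 1e-12) {
    warning("constant image; min-max scaling degenerates to zeros")
    out[] <- 0
  } else {
    out <- (out - rng[1]) / diff(rng)
  }
  structure(out, class = c("bscan", "matrix", "array"),
            pixel_size = c(axial = target_pixel_size[1],
                           mediolateral = target_pixel_size[2]))
}

#' Convert logMAR visual acuity to letter scores
#'
#' ETDRS-style conversion `letters = round(85 - 50 * logMAR)`, clipped to
#' the chart range 5-95.
#' @param logmar finite numeric vector.
#' @return integer letter scores in `[5, 95]`.
#' @examples
#' logmar_to_letters(0)     # 85
#' logmar_to_letters(1.7)   # clipped to 5
#' @export
logmar_to_letters <- function(logmar) {
  if (any(!is.finite(logmar))) stop("non-finite logMAR value")
  pmin(pmax(round(85 - 50 * logmar), 5), 95)
}

#' @rdname logmar_to_letters
#' @param letters letter scores.
#' @export
letters_to_logmar <- function(letters) (85 - letters) / 50

#' Read / write a grayscale image as PNG
#' @param path file path.
#' @param image numeric matrix in `[0, 1]`.
#' @return `read_bscan_png` returns a numeric matrix in `[0, 1]`.
#' @export
write_bscan_png <- function(image, path) {
  png::writePNG(pmin(pmax(unclass(image), 0), 1), path)
  invisible(path)
}

#' @rdname write_bscan_png
#' @export
read_bscan_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 2) stop("color PNG rejected: expected grayscale")
    img <- img[, , 1]
  }
  img
}

#' Per-image min-max scaling of an image stack
#'
#' Applies the per-image intensity standardization of [standardize_bscan()]
#' (without resampling) to a whole stack: each image is independently
#' rescaled to span `[0, 1]`. This is the first step of the analysis
#' pipeline; it removes global brightness/gain differences between
#' acquisitions before contrastive pretraining and before any pixel-space
#' baseline.
#'
#' @param images `(H x W x N)` array.
#' @return array of the same shape; constant images become all zeros.
#' @export
standardize_images <- function(images) {
  stopifnot(is.array(images), length(dim(images)) == 3)
  for (i in seq_len(dim(images)[3])) {
    x <- images[, , i]
    r <- range(x)
    images[, , i] <- if (diff(r) > 1e-12) (x - r[1]) / diff(r) else 0
  }
  images
}
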