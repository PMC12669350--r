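#' qBEI grey-level to calcium calibration
#'
#' Quantitative backscattered electron imaging (qBEI) encodes the local mean
#' atomic number of a polished, carbon-coated bone surface in the 8-bit grey
#' level of the detector image: the brighter the pixel, the higher the local
#' calcium concentration. Calibration uses two high-purity reference standards,
#' carbon (Z = 6) and aluminum (Z = 13), whose measured mean grey values anchor
#' an affine map from grey level to mean atomic number Zbar. A second affine
#' segment maps Zbar to weight-percent calcium, anchored at the osteoid
#' (unmineralized organic matrix) and fully mineralized hydroxyapatite
#' compositions. The composition of the two segments is itself affine and
#' strictly increasing, so the calibration is invertible and round-trips
#' through 8-bit quantization within one grey step.
#'
#' @param grey_carbon Mean grey value of the carbon standard (0-255).
#' @param grey_aluminum Mean grey value of the aluminum standard (0-255);
#'   must exceed `grey_carbon`.
#' @param z_carbon,z_aluminum Atomic numbers of the reference standards.
#' @param z_osteoid Mean atomic number assigned to osteoid (0 wt% Ca anchor).
#' @param z_hydroxyapatite Mean atomic number of hydroxyapatite, the fully
#'   mineralized anchor.
#' @param ca_osteoid,ca_hydroxyapatite Calcium concentrations (wt% Ca) at the
#'   two Zbar anchors; defaults 0 and 39.86 (stoichiometric hydroxyapatite).
#'
#' @return An object of class `qbei_calibration` with elements
#'   `grey_carbon`, `grey_aluminum`, the anchor constants, and the composed
#'   affine coefficients `intercept` and `slope` (wt% Ca per grey level).
#' @examples
#' cal <- fit_calibration(25, 225)
#' ca_from_grey(cal, c(25, 125, 225))
#' @export
fit_calibration <- function(grey_carbon, grey_aluminum,
                            z_carbon = 6.0, z_aluminum = 13.0,
                            z_osteoid = 7.0, z_hydroxyapatite = 14.06,
                            ca_osteoid = 0, ca_hydroxyapatite = 39.86) {
  stopifnot(is.numeric(grey_carbon), is.numeric(grey_aluminum))
  if (!(grey_carbon >= 0 && grey_aluminum <= 255 && grey_carbon < grey_aluminum))
    stop("invalid calibration: need 0 <= grey_carbon < grey_aluminum <= 255")
  if (!(z_aluminum > z_carbon && z_hydroxyapatite > z_osteoid &&
        ca_hydroxyapatite > ca_osteoid))
    stop("invalid calibration: anchor constants must be strictly ordered")

  # grey -> Zbar
  slope_z <- (z_aluminum - z_carbon) / (grey_aluminum - grey_carbon)
  int_z <- z_carbon - slope_z * grey_carbon
  # Zbar -> wt% Ca
  slope_ca <- (ca_hydroxyapatite - ca_osteoid) / (z_hydroxyapatite - z_osteoid)
  int_ca <- ca_osteoid - slope_ca * z_osteoid

  structure(list(
    grey_carbon = grey_carbon, grey_aluminum = grey_aluminum,
    z_carbon = z_carbon, z_aluminum = z_aluminum,
    z_osteoid = z_osteoid, z_hydroxyapatite = z_hydroxyapatite,
    ca_osteoid = ca_osteoid, ca_hydroxyapatite = ca_hydroxyapatite,
    slope = slope_ca * slope_z,
    intercept = int_ca + slope_ca * int_z
  ), class = "qbei_calibration")
}

#' @export
print.qbei_calibration <- function(x, ...) {
  cat("qBEI calibration curve\n")
  cat(sprintf("  grey anchors : C = %.1f, Al = %.1f\n",
              x$grey_carbon, x$grey_aluminum))
  cat(sprintf("  Ca(grey) = %.4f + %.4f * grey  [wt%% Ca, clamped at 0]\n",
              x$intercept, x$slope))
  cat(sprintf("  quantization step: %.4f wt%% Ca per grey level\n", x$slope))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' `ca_from_grey()` maps grey levels to calcium concentration (values mapped
#' below zero by the affine composition are clamped to 0: sub-osteoid greys
#' are background or embedding resin). `grey_from_ca()` is the inverse map
#' without quantization; `grey_from_ca(..., quantize = TRUE)` rounds to the
#' nearest representable 8-bit grey level, which is how the synthetic phantom
#' renderer produces images.
#'
#' @param curve A `qbei_calibration` object.
#' @param grey,ca Numeric vectors of grey values / calcium concentrations.
#' @param quantize Round the grey level to the nearest integer in \[0, 255\]?
#' @return Numeric vector.
#' @export
ca_from_grey <- function(curve, grey) {
  stopifnot(inherits(curve, "qbei_calibration"))
  out <- curve$intercept + curve$slope * grey
  out[out < 0] <- 0
  out
}

#' @rdname ca_from_grey
#' @export
grey_from_ca <- function(curve, ca, quantize = FALSE) {
  stopifnot(inherits(curve, "qbei_calibration"))
  g <- (ca - curve$intercept) / curve$slope
  if (quantize) {
    g <- round(g)
    g[g < 0] <- 0
    g[g > 255] <- 255
  }
  g
}

#' Construct a grey-level qBEI image
#'
#' Bundles an 8-bit pixel matrix with its physical pixel size and a
#' compartment mask. The mask uses integer labels 0 = outside (marrow,
#' resin, off-sample), 1 = cancellous, 2 = cortical; helper label names are
#' accepted everywhere a compartment is requested.
#'
#' @param pixels Integer matrix of grey values in \[0, 255\].
#' @param pixel_size Pixel edge length in micrometers (1.8 for BMDD overview
#'   images, 0.88 for OLS images).
#' @param mask Integer matrix, same shape as `pixels`; defaults to all
#'   cancellous.
#' @return An object of class `grey_image`.
#' @export
grey_image <- function(pixels, pixel_size, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0 | pixels > 255, na.rm = TRUE))
    stop("grey levels must lie in [0, 255]")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (is.null(mask)) mask <- matrix(1L, nrow(pixels), ncol(pixels))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(pixels)))
    stop("mask must have the same shape as pixels")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 mask = mask), class = "grey_image")
}

.compartment_code <- function(compartment) {
  if (is.character(compartment)) {
    code <- c(outside = 0L, cancellous = 1L, cortical = 2L)[compartment]
    if (any(is.na(code))) stop("unknown compartment label: ", compartment)
    unname(code)
  } else as.integer(compartment)
}

#' Apply a calibration curve to a grey-level image
#'
#' Converts every in-mask pixel to a local calcium concentration; pixels
#' outside the compartment mask are undefined (`NA`). The mineralization
#' threshold separating mineralized matrix from voids and osteoid travels with
#' the calibrated image and is used consistently by the BMDD and OLS modules.
#'
#' @param image A [grey_image()].
#' @param curve A [fit_calibration()] curve.
#' @param mineralization_threshold wt% Ca boundary between void/osteoid and
#'   mineralized matrix; default 5.2 wt% Ca, the osteocyte-lacuna
#'   segmentation threshold.
#' @return An object of class `ca_image` with elements `ca` (matrix, wt% Ca,
#'   `NA` outside the mask), `pixel_size`, `mask`,
#'   `mineralization_threshold`.
#' @export
apply_calibration <- function(image, curve, mineralization_threshold = 5.2) {
  stopifnot(inherits(image, "grey_image"), inherits(curve, "qbei_calibration"))
  ca <- ca_from_grey(curve, image$pixels)
  ca[image$mask == 0L] <- NA_real_
  ca_image(ca, image$pixel_size, image$mask, mineralization_threshold)
}

#' Construct a calibrated calcium image directly
#'
#' @param ca Matrix of wt% Ca values (`NA` outside the mask).
#' @param pixel_size Micrometers per pixel.
#' @param mask Compartment label matrix (0/1/2); defaults to all cancellous.
#' @param mineralization_threshold wt% Ca; pixels at or above it count as
#'   mineralized matrix, below it as void/osteoid.
#' @return `ca_image` object.
#' @export
ca_image <- function(ca, pixel_size, mask = NULL, mineralization_threshold = 5.2) {
  ca <- as.matrix(ca)
  if (any(ca < 0, na.rm = TRUE)) stop("calcium concentrations must be >= 0")
  stopifnot(pixel_size > 0)
  if (is.null(mask)) mask <- matrix(1L, nrow(ca), ncol(ca))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(ca))) stop("mask must have the same shape as ca")
  structure(list(ca = ca, pixel_size = pixel_size, mask = mask,
                 mineralization_threshold = mineralization_threshold),
            class = "ca_image")
}

#' @export
print.ca_image <- function(x, ...) {
  cat(sprintf("calibrated qBEI image: %d x %d px, %.2f um/px\n",
              nrow(x$ca), ncol(x$ca), x$pixel_size))
  frac <- mean(x$ca[x$mask > 0] >= x$mineralization_threshold, na.rm = TRUE)
  cat(sprintf("  mineralized fraction of tissue area: %.1f%% (threshold %.1f wt%% Ca)\n",
              100 * frac, x$mineralization_threshold))
  invisible(x)
}
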