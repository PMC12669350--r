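#' Read a grey-level qBEI image from TIFF or PNG
#'
#' Single-channel 8-bit images; values are rescaled from the unit range the
#' readers deliver back to 0-255 grey levels. Masks are label images of
#' identical shape (0 = outside, 1 = cancellous, 2 = cortical).
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @param pixel_size Micrometers per pixel.
#' @param mask_path Optional label image.
#' @return A [grey_image()].
#' @export
read_grey_image <- function(path, pixel_size, mask_path = NULL) {
  read_one <- function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      m <- png::readPNG(p)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      m <- tiff::readTIFF(p)
    }
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  }
  pixels <- round(read_one(path) * 255)
  mask <- if (!is.null(mask_path)) round(read_one(mask_path) * 255)
  grey_image(pixels, pixel_size, mask)
}

#' Write a calibrated calcium map as floating-point TIFF
#'
#' @param image A [ca_image()].
#' @param path Output `.tif` path; `NA` pixels (outside the mask) are
#'   written as 0.
#' @export
write_ca_image <- function(image, path) {
  stopifnot(inherits(image, "ca_image"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF requires the 'tiff' package")
  m <- image$ca
  m[is.na(m)] <- 0
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 32)
  invisible(path)
}

#' Read and write BMDD curves as CSV
#'
#' Curve files have columns `bin_center`, `frequency`; the uniform bin width
#' is recovered from the grid.
#'
#' @param curve A `bmdd_curve`.
#' @param path CSV path.
#' @param compartment Compartment label to attach on read.
#' @return `write_bmdd_curve` returns the path; `read_bmdd_curve` a
#'   `bmdd_curve`.
#' @export
write_bmdd_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bmdd_curve
#' @export
read_bmdd_curve <- function(path, compartment = "cancellous") {
  d <- utils::read.csv(path)
  stopifnot(all(c("bin_center", "frequency") %in% names(d)))
  bw <- stats::median(diff(d$bin_center))
  structure(list(
    bin_edges = c(d$bin_center - bw / 2, max(d$bin_center) + bw / 2),
    bin_centers = d$bin_center,
    frequency = d$frequency,
    compartment = compartment,
    n_pixels = NA_integer_,
    bin_width = bw
  ), class = "bmdd_curve")
}

#' Read Raman spectra listed in a manifest
#'
#' The manifest CSV has columns `file`, `subject`, `compartment`,
#' `position`, `roi_id`, `label_quality`; each referenced file is a
#' two-column CSV (`wavenumber`, `intensity`).
#'
#' @param manifest_path Manifest CSV path; spectrum paths are resolved
#'   relative to it.
#' @return List of [raman_spectrum()] objects with populated metadata.
#' @export
read_raman_manifest <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("file", "subject", "compartment", "position", "roi_id",
              "label_quality")
  stopifnot(all(needed %in% names(man)))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(base, man$file[i]))
    raman_spectrum(d[[1]], d[[2]], meta = as.list(man[i, needed[-1]]))
  })
}
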