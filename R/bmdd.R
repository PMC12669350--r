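#' Bone mineralization density distribution (BMDD)
#'
#' The BMDD is the frequency histogram of local calcium concentrations over
#' the mineralized bone area of a calibrated qBEI image, expressed in percent
#' of mineralized bone area per calcium bin. It is computed for the cancellous
#' and cortical compartments separately. Only pixels at or above the image's
#' mineralization threshold contribute; osteoid and voids are invisible.
#'
#' @param image A [ca_image()].
#' @param compartment Compartment to histogram: `"cancellous"`, `"cortical"`,
#'   or an integer mask label.
#' @param bin_width Histogram bin width in wt% Ca (default 0.17, the
#'   conventional BMDD resolution).
#' @param ca_max Upper edge of the histogram support in wt% Ca.
#' @return An object of class `bmdd_curve`: `bin_edges`, `bin_centers`,
#'   `frequency` (percent of mineralized bone area, summing to 100),
#'   `compartment`, `n_pixels`, `bin_width`.
#' @examples
#' img <- ca_image(matrix(rnorm(1e4, 22, 2), 100), pixel_size = 1.8)
#' curve <- compute_bmdd(img, "cancellous")
#' head(as.data.frame(curve))
#' @export
compute_bmdd <- function(image, compartment = "cancellous",
                         bin_width = 0.17, ca_max = 45) {
  stopifnot(inherits(image, "ca_image"))
  code <- .compartment_code(compartment)
  ca <- image$ca[image$mask == code]
  ca <- ca[!is.na(ca) & ca >= image$mineralization_threshold]
  if (length(ca) == 0)
    stop("empty compartment: no mineralized pixels in '", compartment, "'")
  edges <- seq(0, by = bin_width, length.out = ceiling(ca_max / bin_width) + 1L)
  if (max(ca) >= edges[length(edges)])
    edges <- seq(0, by = bin_width,
                 length.out = floor(max(ca) / bin_width) + 2L)
  counts <- tabulate(findInterval(ca, edges), nbins = length(edges) - 1L)
  structure(list(
    bin_edges = edges,
    bin_centers = edges[-length(edges)] + bin_width / 2,
    frequency = 100 * counts / length(ca),
    compartment = if (is.character(compartment)) compartment else
      c("outside", "cancellous", "cortical")[code + 1L],
    n_pixels = length(ca),
    bin_width = bin_width
  ), class = "bmdd_curve")
}

#' @export
as.data.frame.bmdd_curve <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, frequency = x$frequency)
}

#' @export
print.bmdd_curve <- function(x, ...) {
  cat(sprintf("BMDD curve (%s): %d mineralized px, bin width %.2f wt%% Ca\n",
              x$compartment, x$n_pixels, x$bin_width))
  invisible(x)
}

# interpolated percentile of a binned distribution: frequency is assumed
# uniform within each bin, so the CDF is piecewise linear on bin edges
.bmdd_quantile <- function(curve, p) {
  cdf <- c(0, cumsum(curve$frequency))
  vapply(p, function(pp) {
    target <- pp * 100
    i <- which(cdf[-1] >= target - 1e-12)[1]
    if (is.na(i)) return(curve$bin_edges[length(curve$bin_edges)])
    lo <- cdf[i]
    frac <- if (curve$frequency[i] > 0) (target - lo) / curve$frequency[i] else 0
    curve$bin_edges[i] + frac * curve$bin_width
  }, numeric(1))
}

# percent of area strictly below a calcium cutoff, with linear interpolation
# inside the bin containing the cutoff (the exact inverse of .bmdd_quantile)
.bmdd_area_below <- function(curve, cutoff) {
  edges <- curve$bin_edges
  if (cutoff <= edges[1]) return(0)
  if (cutoff >= edges[length(edges)]) return(100)
  i <- findInterval(cutoff, edges)
  full <- if (i > 1) sum(curve$frequency[seq_len(i - 1L)]) else 0
  full + curve$frequency[i] * (cutoff - edges[i]) / curve$bin_width
}

#' Pool a reference cohort of BMDD curves
#'
#' Pools per-subject BMDD curves (each subject one statistical unit, weighted
#' equally regardless of pixel count) into a single reference distribution
#' and derives the 5th/95th calcium percentile cutoffs used by the `CaLow` /
#' `CaHigh` parameters. Percentiles are interpolated linearly within bins.
#'
#' @param curves List of [compute_bmdd()] curves on identical bin grids.
#' @param probs Lower/upper tail probabilities; default `c(0.05, 0.95)`.
#' @return An object of class `bmdd_reference`: `pooled` (a `bmdd_curve`),
#'   `ca_p5`, `ca_p95`, `n_subjects`.
#' @export
pool_reference <- function(curves, probs = c(0.05, 0.95)) {
  stopifnot(length(curves) >= 2, all(vapply(curves, inherits, TRUE, "bmdd_curve")))
  edges <- curves[[1]]$bin_edges
  for (cv in curves[-1])
    if (length(cv$bin_edges) != length(edges) ||
        max(abs(cv$bin_edges - edges)) > 1e-9)
      stop("grid mismatch: all reference curves must share one bin grid")
  freq <- rowMeans(vapply(curves, `[[`, numeric(length(edges) - 1L), "frequency"))
  freq <- 100 * freq / sum(freq)
  pooled <- curves[[1]]
  pooled$frequency <- freq
  pooled$n_pixels <- sum(vapply(curves, `[[`, integer(1), "n_pixels"))
  pooled$compartment <- "pooled reference"
  q <- .bmdd_quantile(pooled, probs)
  structure(list(pooled = pooled, ca_p5 = q[1], ca_p95 = q[2],
                 n_subjects = length(curves)),
            class = "bmdd_reference")
}

#' @export
print.bmdd_reference <- function(x, ...) {
  cat(sprintf("pooled BMDD reference: n = %d subjects, Ca p5 = %.2f, p95 = %.2f wt%%\n",
              x$n_subjects, x$ca_p5, x$ca_p95))
  invisible(x)
}

#' Derive the five BMDD parameters
#'
#' From a BMDD curve and reference percentile cutoffs:
#' \describe{
#'   \item{CaMean}{frequency-weighted mean calcium concentration (wt% Ca).}
#'   \item{CaPeak}{the most frequent calcium concentration, i.e. the center of
#'     the maximum-frequency bin (ties broken toward the lowest calcium bin).}
#'   \item{CaWidth}{full width at half maximum of the curve (wt% Ca), a
#'     heterogeneity-of-mineralization measure; half-maximum crossings are
#'     linearly interpolated and, for multimodal curves, the outermost
#'     crossings around the global peak are used.}
#'   \item{CaLow}{percent of mineralized bone area below the reference 5th
#'     percentile cutoff.}
#'   \item{CaHigh}{percent of mineralized bone area above the reference 95th
#'     percentile cutoff.}
#' }
#'
#' @param curve A [compute_bmdd()] curve.
#' @param reference A [pool_reference()] object (or any list with `ca_p5`,
#'   `ca_p95`).
#' @return A one-row `data.frame` with columns `CaMean`, `CaPeak`, `CaWidth`,
#'   `CaLow`, `CaHigh`.
#' @export
derive_params <- function(curve, reference) {
  stopifnot(inherits(curve, "bmdd_curve"))
  f <- curve$frequency
  ctr <- curve$bin_centers
  ca_mean <- sum(f * ctr) / sum(f)
  ipk <- which.max(f)          # which.max takes the first (lowest-Ca) tie
  ca_peak <- ctr[ipk]
  half <- f[ipk] / 2

  # outermost half-maximum crossings, piecewise-linear through bin centers
  at_or_above <- which(f >= half)
  jl <- min(at_or_above)
  left <- if (jl > 1L)
    ctr[jl - 1L] + (half - f[jl - 1L]) / (f[jl] - f[jl - 1L]) * curve$bin_width
  else ctr[1L]
  jr <- max(at_or_above)
  right <- if (jr < length(f))
    ctr[jr] + (f[jr] - half) / (f[jr] - f[jr + 1L]) * curve$bin_width
  else ctr[length(ctr)]
  ca_width <- right - left

  data.frame(
    CaMean = ca_mean,
    CaPeak = ca_peak,
    CaWidth = ca_width,
    CaLow = .bmdd_area_below(curve, reference$ca_p5),
    CaHigh = 100 - .bmdd_area_below(curve, reference$ca_p95)
  )
}

#' Mineralized area fraction (md.BV/TV analogue)
#'
#' Percentage of the in-mask tissue area occupied by mineralized matrix
#' (pixels at or above the mineralization threshold). On a 2D section this is
#' the areal analogue of mineralized bone volume per tissue volume.
#'
#' @param image A [ca_image()].
#' @param compartment Compartment label.
#' @return Percent, in \[0, 100\].
#' @export
mineralized_area_fraction <- function(image, compartment = "cancellous") {
  stopifnot(inherits(image, "ca_image"))
  code <- .compartment_code(compartment)
  ca <- image$ca[image$mask == code]
  if (length(ca) == 0) stop("empty compartment mask: '", compartment, "'")
  100 * sum(!is.na(ca) & ca >= image$mineralization_threshold) / length(ca)
}
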