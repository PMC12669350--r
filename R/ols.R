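#' Osteocyte lacunae section (OLS) morphometry
#'
#' Osteocyte lacunae appear in calibrated qBEI images as small voids
#' (calcium below the mineralization threshold, nominally 5.2 wt% Ca)
#' embedded in mineralized matrix. Segmentation groups void pixels into
#' 8-connected components, fills internal holes (a lacuna section is simply
#' connected), and applies the three morphometric filters: components
#' touching the image or compartment-mask border are discarded (they cannot
#' be distinguished from marrow space or resin), components with area outside
#' \[`min_area`, `max_area`\] square micrometers are discarded (larger voids
#' are vascular channels or cracks, smaller ones noise), and components with
#' fitted-ellipse aspect ratio above `max_aspect_ratio` are discarded.
#'
#' @param image A [ca_image()] at OLS resolution (nominally 0.88 um/pixel).
#' @param compartment Compartment label to segment within.
#' @param min_area,max_area Retained section area range in square
#'   micrometers (defaults 5 and 200).
#' @param max_aspect_ratio Upper bound on the fitted-ellipse axis ratio
#'   (default 10).
#' @param threshold Void threshold in wt% Ca; defaults to the image's
#'   mineralization threshold. Comparison is strict (`ca < threshold`), the
#'   exact complement of the mineralized-matrix definition.
#' @param fill_holes Fill enclosed holes inside void components before
#'   measuring? Default `TRUE`.
#' @return A `data.frame` with one row per retained lacuna section:
#'   `area` (um^2), `perimeter` (um), `aspect_ratio`, `centroid_x`,
#'   `centroid_y` (um, x along columns), `n_pixels`, `compartment`.
#' @export
segment_ols <- function(image, compartment = "cancellous",
                        min_area = 5, max_area = 200, max_aspect_ratio = 10,
                        threshold = NULL, fill_holes = TRUE) {
  stopifnot(inherits(image, "ca_image"))
  if (is.null(image$pixel_size) || !is.finite(image$pixel_size))
    stop("configuration error: pixel size is required for OLS morphometry")
  code <- .compartment_code(compartment)
  comp_name <- if (is.character(compartment)) compartment else
    c("outside", "cancellous", "cortical")[code + 1L]
  in_comp <- image$mask == code
  if (!any(in_comp)) stop("empty compartment mask: '", compartment, "'")
  void <- in_comp & !is.na(image$ca) & image$ca < image_threshold(image, threshold)
  empty <- data.frame(area = numeric(0), perimeter = numeric(0),
                      aspect_ratio = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), n_pixels = integer(0),
                      compartment = character(0))
  if (!any(void)) return(empty)

  if (fill_holes)
    void <- EBImage::fillHull(void * 1L) > 0 & in_comp
  lab <- label_components(void)
  n_lab <- max(lab)
  if (n_lab == 0) return(empty)

  # labels touching the image border or 8-adjacent to out-of-compartment pixels
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  out <- !in_comp
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    touching <- .shift_mat(out, dr, dc) & lab > 0
    if (any(touching)) border_labels <- union(border_labels, unique(lab[touching]))
  }
  border_labels <- setdiff(border_labels, 0L)

  s <- image$pixel_size
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  recs <- lapply(setdiff(seq_len(n_lab), border_labels), function(k) {
    coords <- idx[labs == k, , drop = FALSE]
    npx <- nrow(coords)
    area <- npx * s^2
    if (area < min_area || area > max_area) return(NULL)
    ar <- fit_ellipse_aspect_ratio(coords)
    if (!is.finite(ar) || ar > max_aspect_ratio) return(NULL)
    data.frame(
      area = area,
      perimeter = measure_perimeter(coords, s),
      aspect_ratio = ar,
      centroid_x = mean(coords[, 2]) * s,
      centroid_y = mean(coords[, 1]) * s,
      n_pixels = npx,
      compartment = comp_name
    )
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) return(empty)
  do.call(rbind, recs)
}

image_threshold <- function(image, threshold = NULL) {
  if (is.null(threshold)) image$mineralization_threshold else threshold
}

#' Label connected components of a binary mask
#'
#' 8-connected labeling (default) built on [EBImage::bwlabel()] (which is
#' 4-connected) followed by a union-find merge of diagonally adjacent
#' components. 8-connectivity preserves thin, elongated lacuna sections whose
#' digitized outline steps diagonally.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  # collect diagonally adjacent label pairs and merge with union-find
  pairs <- NULL
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nrow(lab) - 1), seq_len(ncol(lab) - 1) + (dd[2] < 0), drop = FALSE]
    b <- lab[seq_len(nrow(lab) - 1) + 1, seq_len(ncol(lab) - 1) + (dd[2] > 0), drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

.shift_mat <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rs_src <- rs - dr; cs_src <- cs - dc
  ok_r <- rs_src >= 1 & rs_src <= nrow(m)
  ok_c <- cs_src >= 1 & cs_src <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[rs_src[ok_r], cs_src[ok_c]]
  out
}

#' Fitted-ellipse aspect ratio of a pixel component
#'
#' Ratio of the long over the short half-axis of the equivalent ellipse,
#' computed as the square root of the eigenvalue ratio of the central
#' second-moment matrix of the pixel coordinates. A value of 1 indicates a
#' perfect circle; larger values an increasingly elongated section.
#' Degenerate (collinear) components return `Inf` and are removed by the
#' aspect-ratio filter upstream.
#'
#' @param coords Two-column matrix of pixel (row, col) coordinates,
#'   at least 3 pixels.
#' @return Aspect ratio `>= 1` (possibly `Inf`).
#' @export
fit_ellipse_aspect_ratio <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  if (nrow(coords) < 3) return(Inf)
  x <- coords[, 1] - mean(coords[, 1])
  y <- coords[, 2] - mean(coords[, 2])
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 + 4 * sxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l2 <= .Machine$double.eps * tr) return(Inf)
  sqrt(l1 / l2)
}

#' Perimeter of a pixel component
#'
#' Boundary length estimated by tracing the 8-connected outer contour
#' (Moore neighborhood tracing) and summing step weights of 1 for edge moves
#' and sqrt(2) for diagonal moves, plus a sharp-corner offset correction:
#' at every contour vertex where the chain turns by 90 degrees or more, half
#' the signed exterior angle (in pixel units) is added. The correction
#' accounts for the half-pixel gap between boundary pixel centers and the
#' true outline at genuine corners; along smooth digitized edges the
#' staircase excess of the chain already compensates that gap, so shallow
#' (45 degree) staircase turns are left uncorrected. Degenerate contours
#' (fewer than three traced points, e.g. a single pixel) fall back to the
#' exposed-edge (crack) perimeter, so one pixel yields `4 * pixel_size`.
#'
#' @param coords Two-column matrix of pixel (row, col) coordinates of one
#'   connected component.
#' @param pixel_size Micrometers per pixel.
#' @return Perimeter in micrometers.
#' @export
measure_perimeter <- function(coords, pixel_size) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, pixel_size > 0)
  # work in a tight window padded by one background row/col on every side
  r0 <- min(coords[, 1]) - 2L; c0 <- min(coords[, 2]) - 2L
  B <- matrix(FALSE, max(coords[, 1]) - r0 + 1L, max(coords[, 2]) - c0 + 1L)
  B[cbind(coords[, 1] - r0, coords[, 2] - c0)] <- TRUE
  contour <- .moore_contour(B)
  if (nrow(contour) < 3) {
    # crack perimeter: count exposed pixel edges
    exposed <- 4L * nrow(coords) -
      sum(.shift_mat(B, 1, 0) & B) - sum(.shift_mat(B, -1, 0) & B) -
      sum(.shift_mat(B, 0, 1) & B) - sum(.shift_mat(B, 0, -1) & B)
    return(exposed * pixel_size)
  }
  steps <- diff(rbind(contour, contour[1, , drop = FALSE]))
  chain <- sum(ifelse(abs(steps[, 1]) + abs(steps[, 2]) == 2, sqrt(2), 1))
  ang <- atan2(steps[, 1], steps[, 2])
  turn <- diff(c(ang, ang[1]))
  turn <- ((turn + pi) %% (2 * pi)) - pi          # wrap to (-pi, pi]
  turn[turn == -pi] <- pi                          # out-and-back spur: convex spike
  # maximal same-direction run length containing each step, circularly
  code <- round(ang / (pi / 4))
  n <- length(code)
  runs <- rle(code)
  run_len <- inverse.rle(list(lengths = runs$lengths, values = runs$lengths))
  if (length(runs$lengths) > 1 && runs$values[1] == runs$values[length(runs$values)]) {
    l1 <- runs$lengths[1]
    ln <- runs$lengths[length(runs$lengths)]
    run_len[seq_len(l1)] <- l1 + ln
    run_len[seq.int(n - ln + 1L, n)] <- l1 + ln
  }
  # turn[i] sits between step i and step (i %% n) + 1; correct only corners
  # flanked by extended straight runs (a lone cap step is staircase)
  nxt <- c(seq_len(n)[-1], 1L)
  sharp <- abs(turn) >= pi / 2 - 1e-9 & run_len >= 2 & run_len[nxt] >= 2
  (chain + 0.5 * sum(turn[sharp])) * pixel_size
}

# Moore-neighbor boundary tracing with Jacob's stopping criterion.
# B: logical matrix padded with a FALSE border. Returns ordered (row, col)
# contour points (duplicates possible on one-pixel-wide arms; steps between
# consecutive points are single 8-neighborhood moves).
.moore_contour <- function(B) {
  # clockwise Moore neighborhood starting west
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  hits <- which(B, arr.ind = TRUE)
  if (nrow(hits) == 0) return(matrix(integer(0), 0, 2))
  # first TRUE in row-major scan: its west neighbor is background
  start <- hits[order(hits[, 1], hits[, 2])[1], ]
  contour <- matrix(start, 1, 2)
  cur <- start
  backtrack <- 1L  # direction index pointing at the west (background) neighbor
  first_move <- NA_integer_
  for (iter in seq_len(8L * nrow(hits) + 8L)) {
    found <- FALSE
    for (k in 0:7) {
      d <- ((backtrack - 1L + k) %% 8L) + 1L
      nb <- cur + dirs[d, ]
      if (B[nb[1], nb[2]]) {
        if (all(cur == start)) {
          if (!is.na(first_move) && d == first_move) return(contour[-nrow(contour), , drop = FALSE])
          if (is.na(first_move)) first_move <- d
        }
        contour <- rbind(contour, nb)
        # new backtrack: direction from nb to the (background) neighbor
        # examined just before d in the clockwise scan
        dprev <- ((d - 2L) %% 8L) + 1L
        v <- dirs[dprev, ] - dirs[d, ]
        backtrack <- which(dirs[, 1] == v[1] & dirs[, 2] == v[2])
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(contour)  # isolated pixel
  }
  contour
}

#' Per-sample OLS summary
#'
#' Aggregates retained lacuna records into the five per-sample,
#' per-compartment OLS parameters. The denominator of density and porosity is
#' the mineralized bone matrix area plus the total OLS area.
#'
#' @param records Output of [segment_ols()].
#' @param mineralized_area Mineralized bone matrix area in mm^2
#'   (see [mineralized_area()]).
#' @return One-row `data.frame`: `n_ols`, `ols_density` (1/mm^2),
#'   `ols_porosity` (%), `ols_area_median` (um^2), `ols_perimeter_median`
#'   (um), `ols_aspect_ratio_median`, `denominator_area` (mm^2). With zero
#'   records, density and porosity are 0 and the medians `NA`.
#' @export
summarize_ols <- function(records, mineralized_area) {
  stopifnot(is.data.frame(records), mineralized_area > 0)
  total_ols_mm2 <- sum(records$area) / 1e6
  denom <- mineralized_area + total_ols_mm2
  data.frame(
    n_ols = nrow(records),
    ols_density = nrow(records) / denom,
    ols_porosity = 100 * total_ols_mm2 / denom,
    ols_area_median = if (nrow(records)) stats::median(records$area) else NA_real_,
    ols_perimeter_median = if (nrow(records)) stats::median(records$perimeter) else NA_real_,
    ols_aspect_ratio_median = if (nrow(records)) stats::median(records$aspect_ratio) else NA_real_,
    denominator_area = denom
  )
}

#' Mineralized matrix area of a compartment
#'
#' @param image A [ca_image()].
#' @param compartment Compartment label.
#' @param units `"mm2"` (default) or `"um2"`.
#' @return Area of pixels at or above the mineralization threshold.
#' @export
mineralized_area <- function(image, compartment = "cancellous", units = "mm2") {
  stopifnot(inherits(image, "ca_image"))
  code <- .compartment_code(compartment)
  ca <- image$ca[image$mask == code]
  n <- sum(!is.na(ca) & ca >= image$mineralization_threshold)
  a <- n * image$pixel_size^2
  switch(match.arg(units, c("mm2", "um2")), mm2 = a / 1e6, um2 = a)
}
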