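#' Synthetic qBEI phantom specification
#'
#' A phantom emulates a calibrated qBEI field: a mineralized matrix whose
#' per-pixel calcium concentrations are Gaussian around a packet mean, with
#' voids carved for elliptical osteocyte lacunae sections, larger pores
#' (vascular channels, area above the lacuna size window) and sub-resolution
#' specks. Every carved object carries analytic ground truth (area =
#' pi*a*b, aspect ratio a/b) so downstream morphometry can be scored without
#' re-derivation.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size Micrometers per pixel (0.88 for OLS-resolution
#'   phantoms, 1.8 for BMDD overview phantoms).
#' @param compartment `"cancellous"` or `"cortical"` (mask label of the
#'   whole field).
#' @param ca_mean,ca_sd Gaussian calcium field parameters (wt% Ca); the
#'   defaults emulate normally mineralized adult bone matrix.
#' @param lacunae `data.frame` with columns `cx`, `cy` (center, pixels),
#'   `a`, `b` (half-axes, micrometers, `a >= b`), `angle` (radians).
#'   Must be pairwise disjoint and inside the image.
#' @param pores Same columns; intended areas above the lacuna window.
#' @param specks `data.frame` with `cx`, `cy`; rendered as 2 x 2 pixel
#'   voids (area below the lacuna window at OLS resolution).
#' @param mineralized_fraction Optional target fraction (0-1): carves the
#'   complement as an unmineralized region so that exactly
#'   `round(fraction * n_pixels)` pixels remain mineralized.
#' @param cement_lines Optional `data.frame` with columns `x0`, `y0`, `x1`,
#'   `y1` (segment endpoints, pixels), `width_px` (1-2) and `ca` (wt% Ca):
#'   narrow low-calcium bands delineating bone packets, as seen in
#'   mineralization defects. Off (`NULL`) by default; they exist to exercise
#'   the OLS border rules and the BMDD low-calcium tail, not as part of the
#'   standard study conditions.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_px = 400, height_px = 400, pixel_size = 0.88,
                         compartment = "cancellous",
                         ca_mean = 21, ca_sd = 1.5,
                         lacunae = NULL, pores = NULL, specks = NULL,
                         mineralized_fraction = NULL, cement_lines = NULL) {
  if (!is.null(cement_lines))
    stopifnot(all(c("x0", "y0", "x1", "y1", "width_px", "ca") %in%
                    names(cement_lines)))
  check_ell <- function(d, what) {
    if (is.null(d) || nrow(d) == 0) return(d)
    stopifnot(all(c("cx", "cy", "a", "b", "angle") %in% names(d)))
    if (any(d$b > d$a)) stop(what, ": half-axes must satisfy a >= b")
    a_px <- d$a / pixel_size
    if (any(d$cx - a_px < 1 | d$cx + a_px > width_px |
            d$cy - a_px < 1 | d$cy + a_px > height_px))
      stop(what, " must lie fully inside the image")
    d
  }
  lacunae <- check_ell(lacunae, "lacunae")
  pores <- check_ell(pores, "pores")
  if (!is.null(lacunae) && nrow(lacunae) > 1) {
    d2 <- as.matrix(stats::dist(lacunae[, c("cx", "cy")])) * pixel_size
    rad <- lacunae$a
    lim <- outer(rad, rad, `+`)
    diag(d2) <- Inf
    if (any(d2 < lim)) stop("overlapping lacunae in phantom spec")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size = pixel_size, compartment = compartment,
                 ca_mean = ca_mean, ca_sd = ca_sd,
                 lacunae = lacunae, pores = pores, specks = specks,
                 mineralized_fraction = mineralized_fraction,
                 cement_lines = cement_lines),
            class = "phantom_spec")
}

#' Deterministic disjoint lacuna placement
#'
#' Places `n` identical ellipses on a jitter-free rectangular grid with a
#' safety margin, guaranteeing disjointness and interior placement.
#'
#' @param n Number of lacunae.
#' @param a,b Half-axes in micrometers.
#' @param angle Radians (recycled).
#' @param spec_width_px,spec_height_px,pixel_size Geometry of the target
#'   phantom.
#' @param margin_px Clearance from the image border (default: half-axis + 4).
#' @return `data.frame` suitable for the `lacunae`/`pores` argument of
#'   [phantom_spec()].
#' @export
place_lacunae <- function(n, a, b = a, angle = 0,
                          spec_width_px = 400, spec_height_px = 400,
                          pixel_size = 0.88,
                          margin_px = ceiling(a / pixel_size) + 4) {
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  xs <- seq(margin_px, spec_width_px - margin_px, length.out = ncol_grid)
  ys <- seq(margin_px, spec_height_px - margin_px, length.out = nrow_grid)
  g <- expand.grid(cx = xs, cy = ys)[seq_len(n), ]
  data.frame(cx = g$cx, cy = g$cy, a = a, b = b,
             angle = rep_len(angle, n), row.names = NULL)
}

# pixels within width_px/2 of the segment (x0,y0)-(x1,y1)
.rasterize_segment <- function(width_px, height_px, x0, y0, x1, y1, seg_width) {
  rr <- seq_len(height_px); cc <- seq_len(width_px)
  px <- outer(rep(1, height_px), cc)
  py <- outer(rr, rep(1, width_px))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- max(vx^2 + vy^2, .Machine$double.eps)
  t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2 <= (seg_width / 2)^2
}

.rasterize_ellipse <- function(width_px, height_px, cx, cy, a_px, b_px, angle) {
  # center-of-pixel inclusion; pixel (r, c) has center (c, r) in x/y order
  rr <- seq_len(height_px); cc <- seq_len(width_px)
  dx <- outer(rep(1, height_px), cc - cx)
  dy <- outer(rr - cy, rep(1, width_px))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

#' Render a qBEI phantom
#'
#' Samples the Gaussian calcium field, carves the voids, and (via the
#' inverse calibration with 8-bit quantization) produces the grey-level
#' image an SEM would deliver, together with its calibrated counterpart and
#' the analytic ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param curve A [fit_calibration()] curve; default `fit_calibration(25, 225)`.
#' @param mineralization_threshold wt% Ca void/matrix boundary.
#' @param seed Optional integer for reproducible fields.
#' @return List with `grey` ([grey_image()]), `ca` ([ca_image()], obtained by
#'   calibrating `grey`), and `truth` (list: `lacunae`, `pores`, `specks`
#'   data frames with `area` (um^2) and `aspect_ratio`; `ca_mean`, `ca_sd`,
#'   `mineralized_fraction`).
#' @export
render_phantom <- function(spec, curve = fit_calibration(25, 225),
                           mineralization_threshold = 5.2, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  h <- spec$height_px; w <- spec$width_px; s <- spec$pixel_size
  ca <- matrix(pmax(0, stats::rnorm(h * w, spec$ca_mean, spec$ca_sd)), h, w)

  if (!is.null(spec$mineralized_fraction)) {
    n_void <- h * w - round(spec$mineralized_fraction * h * w)
    if (n_void > 0) ca[seq_len(n_void)] <- 0  # column-major leading block
  }
  carve <- function(d) {
    if (is.null(d) || nrow(d) == 0) return(invisible())
    for (i in seq_len(nrow(d)))
      ca[.rasterize_ellipse(w, h, d$cx[i], d$cy[i], d$a[i] / s, d$b[i] / s,
                            d$angle[i])] <<- 0
  }
  if (!is.null(spec$cement_lines))
    for (i in seq_len(nrow(spec$cement_lines))) {
      cl <- spec$cement_lines[i, ]
      ca[.rasterize_segment(w, h, cl$x0, cl$y0, cl$x1, cl$y1,
                            cl$width_px)] <- cl$ca
    }
  carve(spec$lacunae)
  carve(spec$pores)
  if (!is.null(spec$specks) && nrow(spec$specks) > 0)
    for (i in seq_len(nrow(spec$specks))) {
      # 2 x 2 px block: measurable yet below the lacuna size window
      rr <- round(spec$specks$cy[i]) + 0:1
      cc <- round(spec$specks$cx[i]) + 0:1
      ca[rr, cc] <- 0
    }

  grey <- grey_image(grey_from_ca(curve, ca, quantize = TRUE), s,
                     mask = matrix(.compartment_code(spec$compartment), h, w))
  ca_img <- apply_calibration(grey, curve, mineralization_threshold)

  truthify <- function(d) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    data.frame(d, area = pi * d$a * d$b, aspect_ratio = d$a / d$b)
  }
  truth <- list(
    lacunae = truthify(spec$lacunae), pores = truthify(spec$pores),
    specks = spec$specks,
    ca_mean = spec$ca_mean, ca_sd = spec$ca_sd,
    mineralized_fraction = if (!is.null(spec$mineralized_fraction))
      round(spec$mineralized_fraction * h * w) / (h * w)
  )
  list(grey = grey, ca = ca_img, truth = truth)
}

#' Synthetic Raman spectrum specification
#'
#' Bands are Gaussian or Lorentzian peaks parameterized by peak amplitude,
#' center and width (Gaussian sigma or Lorentzian half-width gamma), summed
#' over a smooth convex fluorescence background polynomial plus white noise.
#' The defaults emulate a typical baseline-corrected bone spectrum: v2PO4
#' (~430), embedding resin (~501), v1PO4 (~960), amide III (~1256),
#' proteoglycan CH3 (~1377), amide I (~1660).
#'
#' @param bands `data.frame` with columns `shape` (`"gaussian"` or
#'   `"lorentzian"`), `center`, `width`, `amplitude`.
#' @param background Polynomial coefficients `c(b0, b1, b2)` in wavenumber;
#'   keep the quadratic coefficient non-negative (fluorescence backgrounds
#'   are broad and convex) so the rubber band can remove it.
#' @param noise_sd Noise standard deviation as a fraction of the largest
#'   band amplitude.
#' @param grid Wavenumber grid (must cover 350-1800 1/cm with margin).
#' @return Object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(bands = default_bone_bands(),
                          background = c(60, -0.035, 1.0e-5),
                          noise_sd = 0.01,
                          grid = seq(300, 1900, by = 1)) {
  stopifnot(all(c("shape", "center", "width", "amplitude") %in% names(bands)),
            all(bands$shape %in% c("gaussian", "lorentzian")),
            min(grid) <= 350, max(grid) >= 1800)
  structure(list(bands = bands, background = background,
                 noise_sd = noise_sd, grid = grid),
            class = "spectrum_spec")
}

#' Default synthetic bone band inventory
#'
#' Peak amplitudes are in arbitrary intensity units; widths chosen so that
#' neighbouring bands are spectrally resolved (inter-band valleys reach the
#' background), as in measured bone spectra after polishing.
#' @export
default_bone_bands <- function() {
  data.frame(
    shape = c("gaussian", "gaussian", "gaussian", "gaussian", "gaussian",
              "gaussian"),
    name = c("v2PO4", "embedding", "v1PO4", "amideIII", "CH3", "amideI"),
    center = c(430, 501.5, 960, 1256, 1377, 1660),
    width = c(14, 5, 8, 20, 7, 18),
    amplitude = c(55, 14, 100, 32, 11, 38)
  )
}

.band_profile <- function(shape, center, width, amplitude, x) {
  switch(shape,
         gaussian = amplitude * exp(-(x - center)^2 / (2 * width^2)),
         lorentzian = amplitude * width^2 / ((x - center)^2 + width^2))
}

# closed-form band area over [lo, hi]
.band_window_area <- function(shape, center, width, amplitude, lo, hi) {
  switch(shape,
         gaussian = amplitude * width * sqrt(2 * pi) *
           (stats::pnorm((hi - center) / width) - stats::pnorm((lo - center) / width)),
         lorentzian = amplitude * width *
           (atan((hi - center) / width) - atan((lo - center) / width)))
}

#' Analytic Raman metrics of a spectrum specification
#'
#' Closed-form values of the five metrics implied by the generating bands
#' (background and noise excluded): window areas are sums of the erf/arctan
#' partial integrals of every band over the metric's window, the Pyd height
#' is the noiseless composite band intensity at 1660 1/cm, and the
#' crystallinity is the closed-form FWHM (2.3548 sigma or 2 gamma) of the
#' band centered in the v1PO4 window.
#'
#' @param spec A [spectrum_spec()].
#' @return One-row `data.frame` with `mm`, `gag`, `nanoporosity`, `pyd`,
#'   `mmc`.
#' @export
analytic_raman_params <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  b <- spec$bands
  win <- raman_band_windows()
  warea <- function(wd) sum(mapply(.band_window_area, b$shape, b$center,
                                   b$width, b$amplitude,
                                   MoreArgs = list(lo = wd[1], hi = wd[2])))
  amide3 <- warea(win$amideIII)
  h1660 <- sum(mapply(.band_profile, b$shape, b$center, b$width, b$amplitude,
                      MoreArgs = list(x = 1660)))
  iv1 <- which(b$center > win$v1PO4[1] & b$center < win$v1PO4[2])
  stopifnot(length(iv1) == 1)
  fwhm <- if (b$shape[iv1] == "gaussian")
    2 * sqrt(2 * log(2)) * b$width[iv1] else 2 * b$width[iv1]
  data.frame(
    mm = warea(win$v2PO4) / amide3,
    gag = warea(win$CH3) / amide3,
    nanoporosity = warea(win$embedding) / amide3,
    pyd = h1660 / warea(win$amideI),
    mmc = 1 / fwhm
  )
}

#' Render a synthetic Raman spectrum
#'
#' @param spec A [spectrum_spec()].
#' @param meta Metadata list passed to the spectrum.
#' @param seed Optional integer for a reproducible noise realization.
#' @return List with `spectrum` (raw [raman_spectrum()] including background
#'   and noise) and `truth` ([analytic_raman_params()]).
#' @export
render_spectrum <- function(spec, meta = list(), seed = NULL) {
  stopifnot(inherits(spec, "spectrum_spec"))
  if (!is.null(seed)) set.seed(seed)
  x <- spec$grid
  b <- spec$bands
  y <- rowSums(mapply(.band_profile, b$shape, b$center, b$width, b$amplitude,
                      MoreArgs = list(x = x)))
  bg <- spec$background[1] + spec$background[2] * x + spec$background[3] * x^2
  noise <- if (spec$noise_sd > 0)
    stats::rnorm(length(x), 0, spec$noise_sd * max(b$amplitude)) else 0
  list(spectrum = raman_spectrum(x, y + bg + noise, meta),
       truth = analytic_raman_params(spec))
}

#' Simulate a reference cohort of BMDD curves
#'
#' Each subject contributes one BMDD curve computed from a Gaussian calcium
#' pixel field; subject means are themselves Gaussian around the cohort
#' mean, emulating healthy between-subject variability.
#'
#' @param n_subjects Number of subjects (default 25, the size of the
#'   published healthy adult reference cohort).
#' @param n_px Mineralized pixels per subject.
#' @param ca_mean Cohort mean calcium concentration (wt% Ca).
#' @param between_sd Between-subject SD of the subject means.
#' @param within_sd Within-subject pixel SD.
#' @param seed Optional integer.
#' @param ... Passed to [compute_bmdd()] (`bin_width`, `ca_max`).
#' @return List of `bmdd_curve` objects.
#' @export
simulate_reference <- function(n_subjects = 25, n_px = 20000,
                               ca_mean = 22.2, between_sd = 0.55,
                               within_sd = 1.5, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mus <- stats::rnorm(n_subjects, ca_mean, between_sd)
  lapply(mus, function(mu) {
    side <- ceiling(sqrt(n_px))
    img <- ca_image(matrix(pmax(0, stats::rnorm(side^2, mu, within_sd)),
                           side), pixel_size = 1.8)
    compute_bmdd(img, "cancellous", ...)
  })
}

#' Simulate a patient-style cohort with compartment coupling
#'
#' Draws per-subject latent cancellous/cortical mean calcium concentrations
#' from a bivariate normal with correlation `rho` (cancellous and cortical
#' mineralization are tightly coupled within an individual), applies
#' group-specific shifts, renders per-subject Gaussian pixel fields, and
#' returns a tidy per-subject outcome table of the five BMDD parameters per
#' compartment, ready for the gated comparison workflow.
#'
#' @param groups `data.frame` with columns `name`, `n`, `shift` (wt% Ca
#'   added to the latent mean; 0 for reference-like groups). The default
#'   emulates a study design with a small affected subgroup (n = 5, strong
#'   downward mineralization shift), a larger unaffected subgroup (n = 16)
#'   and a healthy reference (n = 25).
#' @param rho Latent between-compartment correlation (default 0.9).
#' @param ca_mean,between_sd,within_sd Field parameters as in
#'   [simulate_reference()].
#' @param n_px Pixels per subject and compartment.
#' @param reference A [pool_reference()] object supplying CaLow/CaHigh
#'   cutoffs; if `NULL`, cutoffs are derived from the simulated reference
#'   group's own curves.
#' @param seed Optional integer.
#' @return List: `params` (tidy `data.frame`: `subject`, `group`,
#'   `compartment`, the five BMDD parameters), `latent` (the generating
#'   means), `reference` (the `bmdd_reference` used).
#' @export
simulate_cohort <- function(groups = data.frame(
                              name = c("GROUP-1", "GROUP-2", "REF"),
                              n = c(5, 16, 25),
                              shift = c(-1.5, 0, 0)),
                            rho = 0.9, ca_mean = 22.2, between_sd = 0.55,
                            within_sd = 1.5, n_px = 10000,
                            reference = NULL, seed = NULL) {
  stopifnot(all(c("name", "n", "shift") %in% names(groups)), all(groups$n >= 3))
  if (!is.null(seed)) set.seed(seed)
  side <- ceiling(sqrt(n_px))
  rows <- list(); curves <- list(); latent <- list()
  subj <- 0L
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$n[g])) {
      subj <- subj + 1L
      z <- stats::rnorm(2)
      z2 <- rho * z[1] + sqrt(1 - rho^2) * z[2]
      mu <- ca_mean + groups$shift[g] + between_sd * c(z[1], z2)
      names(mu) <- c("cancellous", "cortical")
      latent[[subj]] <- data.frame(subject = subj, group = groups$name[g],
                                   mu_cn = mu[1], mu_ct = mu[2])
      for (cmp in c("cancellous", "cortical")) {
        img <- ca_image(matrix(pmax(0, stats::rnorm(side^2, mu[[cmp]], within_sd)),
                               side), pixel_size = 1.8)
        crv <- compute_bmdd(img, "cancellous")
        crv$compartment <- cmp
        curves[[length(curves) + 1L]] <-
          list(subject = subj, group = groups$name[g], compartment = cmp,
               curve = crv)
      }
    }
  }
  if (is.null(reference)) {
    ref_curves <- lapply(Filter(function(e) e$group == "REF" &&
                                  e$compartment == "cancellous", curves),
                         `[[`, "curve")
    if (length(ref_curves) < 2)
      stop("no REF group to derive reference cutoffs from; supply `reference`")
    reference <- pool_reference(ref_curves)
  }
  params <- do.call(rbind, lapply(curves, function(e) {
    cbind(data.frame(subject = e$subject, group = e$group,
                     compartment = e$compartment),
          derive_params(e$curve, reference))
  }))
  rownames(params) <- NULL
  list(params = params, latent = do.call(rbind, latent), reference = reference)
}

#' Canned OLS validation phantom
#'
#' A 600 x 600 px, 0.88 um/pixel phantom holding 40 in-range elliptical
#' lacunae (areas 20-80 um^2, aspect ratios 1.2-3.2), 3 pores with areas
#' above 200 um^2, 5 single-pixel specks below 5 um^2, and one thin ellipse
#' of axis ratio 12. A correct segmentation retains exactly the 40 lacunae:
#' the pores fail the upper size filter, the specks the lower one, and the
#' thin ellipse the aspect-ratio filter.
#'
#' @param pixel_size Micrometers per pixel.
#' @return A [phantom_spec()].
#' @export
ols_validation_phantom <- function(pixel_size = 0.88) {
  areas <- seq(20, 80, length.out = 40)
  ar <- rep(c(1.2, 1.8, 2.5, 3.2), 10)
  a <- sqrt(areas * ar / pi)
  b <- a / ar
  pos <- place_lacunae(40, a = max(a), spec_width_px = 600,
                       spec_height_px = 440, pixel_size = pixel_size)
  lac <- data.frame(cx = pos$cx, cy = pos$cy, a = a, b = b,
                    angle = seq(0, pi, length.out = 40))
  pores <- data.frame(cx = c(80, 300, 520), cy = c(530, 545, 530),
                      a = 10, b = 8, angle = c(0, 0.6, 1.1))
  specks <- data.frame(cx = c(40, 150, 450, 560, 300),
                       cy = c(580, 575, 575, 580, 585))
  thin <- data.frame(cx = 300, cy = 490, a = 9.6, b = 0.8, angle = 0.4)
  phantom_spec(600, 600, pixel_size,
               lacunae = lac, pores = rbind(pores, thin), specks = specks)
}
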