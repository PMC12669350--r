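# shared fixtures, all generated in code

default_cal <- function() fit_calibration(25, 225)

# binary disk/ellipse coordinate sets for morphometry oracles
raster_disk <- function(r, pad = 6) {
  n <- 2 * r + 2 * pad + 1
  ctr <- r + pad + 1
  which(outer(seq_len(n), seq_len(n),
              function(rr, cc) (rr - ctr)^2 + (cc - ctr)^2 <= r^2),
        arr.ind = TRUE)
}

raster_ellipse <- function(a, b, angle = 0, pad = 6) {
  n <- 2 * ceiling(a) + 2 * pad + 1
  ctr <- ceiling(a) + pad + 1
  which(outer(seq_len(n), seq_len(n), function(rr, cc) {
    x <- (cc - ctr) * cos(angle) + (rr - ctr) * sin(angle)
    y <- -(cc - ctr) * sin(angle) + (rr - ctr) * cos(angle)
    (x / a)^2 + (y / b)^2 <= 1
  }), arr.ind = TRUE)
}

# Ramanujan ellipse perimeter (analytic oracle)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# calcium image with a given pixel vector (helper for BMDD tests)
ca_image_from_values <- function(values, pixel_size = 1.8, ...) {
  side <- ceiling(sqrt(length(values)))
  v <- rep(values, length.out = side^2)
  ca_image(matrix(v, side), pixel_size, ...)
}

# single Gaussian band spectrum on a flat/linear background
gaussian_spectrum <- function(center, sigma, amplitude, offset = 0,
                              slope = 0, grid = seq(300, 1900, by = 1)) {
  raman_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * sigma^2)) +
                   offset + slope * grid)
}
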