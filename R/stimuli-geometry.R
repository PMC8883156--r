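#' Procedural bumpy-sphere geometry
#'
#' Stimulus objects are height fields built from a unit sphere whose
#' surface is modulated by one of five noise kinds, mirroring the five
#' study geometries: a low-frequency/crater surface, a bandpass-noise
#' sphere, a sine-modulated sphere, and two Perlin-style multi-octave
#' spheres. All noise is expressed as seeded random cosine sums (plus
#' crater bumps), so the surface is a continuous function of position and
#' can be sampled under any in-plane pose rotation.
#'
#' @param noise_kind one of `"lowfreq_crater"`, `"bandpass"`, `"sine"`,
#'   `"perlin_a"`, `"perlin_b"`.
#' @param amplitude relative bump height (fraction of sphere radius).
#' @param seed integer seed; presets are reproducible from their seeds.
#' @return List of class `geometry_spec`.
#' @export
geometry_spec <- function(noise_kind, amplitude = 0.08, seed = 1L) {
  noise_kind <- match.arg(noise_kind, c("lowfreq_crater", "bandpass",
                                        "sine", "perlin_a", "perlin_b"))
  stopifnot(amplitude >= 0, amplitude < 0.5)
  structure(list(noise_kind = noise_kind, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "geometry_spec")
}

#' @rdname geometry_spec
#' @param object object index 1-5.
#' @export
geometry_preset <- function(object) {
  stopifnot(object %in% 1:5)
  kinds <- c("lowfreq_crater", "bandpass", "sine", "perlin_a", "perlin_b")
  amps <- c(0.10, 0.06, 0.06, 0.08, 0.10)
  geometry_spec(kinds[object], amps[object], seed = 1000L + object)
}

# random cosine-sum noise: J components with |k| drawn in [k_lo, k_hi]
# (radians per unit length), unit-variance-ish, evaluated at (x, y)
cosine_noise <- function(x, y, J, k_lo, k_hi) {
  kmag <- stats::runif(J, k_lo, k_hi)
  kang <- stats::runif(J, 0, 2 * pi)
  phase <- stats::runif(J, 0, 2 * pi)
  kx <- kmag * cos(kang); ky <- kmag * sin(kang)
  out <- 0
  for (j in seq_len(J))
    out <- out + cos(kx[j] * x + ky[j] * y + phase[j])
  out * sqrt(2 / J)
}

# displacement field for a geometry at (possibly rotated) coordinates
noise_displacement <- function(geom, x, y) {
  with_seed(geom$seed, {
    switch(geom$noise_kind,
      lowfreq_crater = {
        base <- cosine_noise(x, y, J = 8, k_lo = pi, k_hi = 3 * pi)
        cx <- stats::runif(6, -0.7, 0.7); cy <- stats::runif(6, -0.7, 0.7)
        cr <- stats::runif(6, 0.12, 0.3)
        craters <- 0
        for (j in 1:6)
          craters <- craters -
            1.6 * exp(-((x - cx[j])^2 + (y - cy[j])^2) / cr[j]^2)
        base + craters
      },
      bandpass = cosine_noise(x, y, J = 60, k_lo = 8 * pi, k_hi = 12 * pi),
      sine = {
        ph <- stats::runif(2, 0, 2 * pi)
        sqrt(2) * sin(5 * pi * x + ph[1]) * sin(7 * pi * y + ph[2])
      },
      perlin_a =
        cosine_noise(x, y, 10, 2 * pi, 4 * pi) +
        0.5 * cosine_noise(x, y, 20, 4 * pi, 8 * pi) +
        0.25 * cosine_noise(x, y, 40, 8 * pi, 16 * pi),
      perlin_b =
        0.6 * cosine_noise(x, y, 10, 2 * pi, 4 * pi) +
        0.7 * cosine_noise(x, y, 20, 6 * pi, 10 * pi) +
        0.5 * cosine_noise(x, y, 40, 12 * pi, 20 * pi))
  })
}

# height field of a posed bumpy sphere on an n x n grid over [-1, 1]^2.
# Returns list(h, mask, nx, ny, nz, thickness); normals from central
# differences, thickness is the sphere chord length (used by the
# translucency proxy).
height_field <- function(geom, n, pose_deg = 0) {
  stopifnot(n >= 32)
  s <- seq(-1, 1, length.out = n)
  x <- matrix(s, n, n)              # column coordinate
  y <- matrix(s, n, n, byrow = TRUE)
  r2 <- x^2 + y^2
  mask <- r2 < 1
  z <- sqrt(pmax(1 - r2, 0))
  th <- pose_deg * pi / 180
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  disp <- noise_displacement(geom, xr, yr)
  h <- z * (1 + geom$amplitude * disp)  # taper modulation to 0 at the rim
  h[!mask] <- 0
  d <- 2 / (n - 1)
  # central differences (edge rows/cols replicated)
  ix <- c(2:n, n); ixm <- c(1, 1:(n - 1))
  dhdx <- (h[ix, ] - h[ixm, ]) / (2 * d)
  dhdy <- (h[, ix] - h[, ixm]) / (2 * d)
  norm <- sqrt(dhdx^2 + dhdy^2 + 1)
  list(h = h, mask = mask,
       nx = -dhdx / norm, ny = -dhdy / norm, nz = 1 / norm,
       thickness = 2 * z)
}
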