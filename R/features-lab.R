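# sRGB (linear) -> XYZ, D65 primaries
.srgb_to_xyz_mat <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                             0.2126729, 0.7151522, 0.0721750,
                             0.0193339, 0.1191920, 0.9503041),
                           3, 3, byrow = TRUE)

#' Convert an 8-bit gamma-encoded image to CIE L*a*b* planes
#'
#' Decodes the display gamma (2.2), converts linear RGB to XYZ with D65
#' primaries, and applies the CIELAB transform against a supplied white
#' point — the XYZ of the scene's diffuse white, obtained by rendering a
#' matte white sphere under the same illumination (see
#' [condition_white_point()]). A pixel whose XYZ equals the white point
#' maps to L* = 100, a* = b* = 0.
#'
#' @param img integer array `H x W x 3`, values 0-255.
#' @param white_point length-3 positive numeric, XYZ of diffuse white.
#' @return List of class `lab_image`: matrices `L`, `a`, `b` and the
#'   `white_point`.
#' @export
rgb_to_lab <- function(img, white_point) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  if (any(white_point <= 0)) stop("white_point must be strictly positive")
  lin <- (img / 255)^2.2
  d <- dim(img)[1:2]
  rgbm <- rbind(as.vector(lin[, , 1]), as.vector(lin[, , 2]),
                as.vector(lin[, , 3]))
  xyz <- .srgb_to_xyz_mat %*% rgbm
  f <- function(t) {
    eps <- (6 / 29)^3
    ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(xyz[1, ] / white_point[1])
  fy <- f(xyz[2, ] / white_point[2])
  fz <- f(xyz[3, ] / white_point[3])
  structure(list(L = matrix(116 * fy - 16, d[1], d[2]),
                 a = matrix(500 * (fx - fy), d[1], d[2]),
                 b = matrix(200 * (fy - fz), d[1], d[2]),
                 white_point = white_point),
            class = "lab_image")
}

# XYZ of an 8-bit RGB triple (used by tests and white-point computation)
rgb_to_xyz <- function(rgb255) {
  as.numeric(.srgb_to_xyz_mat %*% ((rgb255 / 255)^2.2))
}

#' Diffuse-white reference for an illumination condition
#'
#' Renders a matte white sphere (unit albedo, no specular component)
#' under each illumination proxy of the condition and averages the XYZ of
#' the object pixels; this is the white point used for the CIELAB
#' conversion of that condition's stimuli.
#'
#' @param illumination_condition 1, 2 or 3.
#' @param size render size in pixels.
#' @return Length-3 XYZ vector.
#' @export
condition_white_point <- function(illumination_condition, size = 128) {
  proxies <- illum_condition_proxies(illumination_condition)
  sphere <- geometry_spec("sine", amplitude = 0, seed = 1L)
  xyz <- vapply(proxies, function(pr) {
    proxy <- illum_proxy(pr)
    hf <- height_field(sphere, size)
    dl <- diffuse_layer(hf, proxy$lights)
    lin <- vapply(1:3, function(ch) {
      v <- dl[[ch]] + proxy$ambient[ch] / pi
      mean(pmin(pmax(v[hf$mask], 0), 1))
    }, numeric(1))
    as.numeric(.srgb_to_xyz_mat %*% lin)
  }, numeric(3))
  rowMeans(xyz)
}

#' Crop the central window of an image
#'
#' Even margins are split with the floor on the top/left side, so a
#' 512-pixel side cropped to 128 keeps rows/columns 193-320.
#'
#' @param img matrix or `H x W x 3` array, each side >= `size`.
#' @param size side of the square crop (default 128).
#' @return The cropped matrix or array.
#' @export
center_crop <- function(img, size = 128) {
  d <- dim(img)
  if (d[1] < size || d[2] < size)
    stop(sprintf("image (%d x %d) is smaller than the %d-pixel crop",
                 d[1], d[2], size))
  r0 <- floor((d[1] - size) / 2)
  c0 <- floor((d[2] - size) / 2)
  if (length(d) == 3) img[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
  else img[r0 + seq_len(size), c0 + seq_len(size)]
}
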