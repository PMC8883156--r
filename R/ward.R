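#' Ward reflectance model and perceptual gloss parameterization
#'
#' The Ward model describes a glossy surface with three parameters: the
#' diffuse reflectance `rho_d`, the specular energy `rho_s`, and the spread
#' of the specular lobe `alpha`. Pellacini et al.'s perceptual
#' reparameterization replaces (`rho_s`, `alpha`) with two perceptual
#' dimensions: contrast gloss `c` and distinctness-of-image (DOI) gloss `d`,
#'
#' \deqn{d = 1 - \alpha, \qquad
#'       c = (\rho_s + \rho_d/2)^{1/3} - (\rho_d/2)^{1/3}.}
#'
#' `ward_brdf()` constructs a validated parameter tuple; the conversions and
#' the pointwise BRDF evaluation operate on it.
#'
#' @param rho_d diffuse reflectance, in `[0, 1]`.
#' @param rho_s specular energy, in `[0, 1]`; `rho_d + rho_s` must not
#'   exceed 1 (energy conservation).
#' @param alpha specular lobe spread, in `(0, 1]`. Small values give sharp,
#'   mirror-like highlights.
#' @return An object of class `ward_brdf`: a list with fields `rho_d`,
#'   `rho_s`, `alpha`.
#' @examples
#' b <- ward_brdf(rho_d = 0.416, rho_s = 0.12, alpha = 0.06)
#' ward_to_perceptual(b)
#' @export
ward_brdf <- function(rho_d, rho_s, alpha) {
  stopifnot(is.numeric(rho_d), is.numeric(rho_s), is.numeric(alpha))
  if (rho_d < 0 || rho_s < 0)
    stop("rho_d and rho_s must be nonnegative")
  if (rho_d + rho_s > 1 + 1e-12)
    stop("energy conservation violated: rho_d + rho_s > 1")
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  structure(list(rho_d = rho_d, rho_s = rho_s, alpha = alpha),
            class = "ward_brdf")
}

#' @export
print.ward_brdf <- function(x, ...) {
  g <- ward_to_perceptual(x)
  cat(sprintf(
    "Ward BRDF: rho_d = %.4g, rho_s = %.4g, alpha = %.4g (c = %.3f, d = %.2f)\n",
    x$rho_d, x$rho_s, x$alpha, g$c, g$d))
  invisible(x)
}

#' Convert Ward parameters to perceptual gloss (c, d)
#'
#' @param b a [ward_brdf()] object.
#' @return A list of class `perceptual_gloss` with fields `c` (contrast
#'   gloss, nonnegative) and `d` (DOI gloss, `d = 1 - alpha`).
#' @seealso [perceptual_to_ward()] for the inverse.
#' @export
ward_to_perceptual <- function(b) {
  stopifnot(inherits(b, "ward_brdf"))
  if (b$rho_d + b$rho_s > 1 + 1e-12)
    stop("rho_d + rho_s > 1")
  half_d <- b$rho_d / 2
  structure(
    list(c = (b$rho_s + half_d)^(1 / 3) - half_d^(1 / 3),
         d = 1 - b$alpha),
    class = "perceptual_gloss")
}

#' Convert perceptual gloss (c, d) back to Ward parameters
#'
#' Closed-form inverse: `rho_s = (c + (rho_d/2)^(1/3))^3 - rho_d/2` and
#' `alpha = 1 - d`. The diffuse reflectance is not constrained by (c, d)
#' and must be supplied.
#'
#' @param c contrast gloss, nonnegative.
#' @param d DOI gloss, in `[0, 1)`.
#' @param rho_d diffuse reflectance, in `[0, 1]`.
#' @return A [ward_brdf()] object.
#' @export
perceptual_to_ward <- function(c, d, rho_d) {
  stopifnot(c >= 0, d >= 0, d < 1, rho_d >= 0, rho_d <= 1)
  half_d <- rho_d / 2
  rho_s <- (c + half_d^(1 / 3))^3 - half_d
  # tiny negative values from floating-point cancellation are clamped
  if (rho_s < 0) {
    if (rho_s < -1e-12) stop("implied rho_s is negative")
    rho_s <- 0
  }
  if (rho_d + rho_s > 1 + 1e-12)
    stop("implied rho_s violates energy conservation (rho_d + rho_s > 1)")
  ward_brdf(rho_d = rho_d, rho_s = rho_s, alpha = 1 - d)
}

#' Evaluate the Ward BRDF for an incoming/outgoing direction pair
#'
#' \deqn{\rho(\theta_i,\phi_i,\theta_o,\phi_o) = \rho_d/\pi +
#'   \rho_s \frac{\exp(-\tan^2\delta / \alpha^2)}
#'               {4\pi\alpha^2\sqrt{\cos\theta_i\,\cos\theta_o}}}
#'
#' where \eqn{\delta} is the angle between the half vector of the incoming
#' and outgoing directions and the surface normal (the standard Ward
#' convention; the original model leaves \eqn{\delta} implicit).
#' Angles are spherical coordinates about the surface normal: polar angles
#' `theta` in `[0, pi/2)`, azimuths `phi` in `[0, 2*pi)`. Vectorized over
#' direction components.
#'
#' @param b a [ward_brdf()] object.
#' @param theta_i,phi_i incoming direction (radians).
#' @param theta_o,phi_o outgoing direction (radians).
#' @return Reflectance density (1/sr), nonnegative; equals `rho_d / pi`
#'   everywhere when `rho_s = 0`, and satisfies Helmholtz reciprocity.
#' @export
eval_ward <- function(b, theta_i, phi_i, theta_o, phi_o) {
  stopifnot(inherits(b, "ward_brdf"))
  n <- max(length(theta_i), length(phi_i), length(theta_o), length(phi_o))
  theta_i <- rep_len(theta_i, n); phi_i <- rep_len(phi_i, n)
  theta_o <- rep_len(theta_o, n); phi_o <- rep_len(phi_o, n)
  ci <- cos(theta_i)
  co <- cos(theta_o)
  if (any(ci <= 1e-12) || any(co <= 1e-12))
    stop("grazing or below-horizon directions: cos(theta) must be positive")
  # unit vectors; normal is +z
  wi <- cbind(sin(theta_i) * cos(phi_i), sin(theta_i) * sin(phi_i), ci)
  wo <- cbind(sin(theta_o) * cos(phi_o), sin(theta_o) * sin(phi_o), co)
  h <- wi + wo
  hn <- sqrt(rowSums(h^2))
  cos_delta <- h[, 3] / hn
  tan2_delta <- (1 - cos_delta^2) / cos_delta^2
  spec <- b$rho_s * exp(-tan2_delta / b$alpha^2) /
    (4 * pi * b$alpha^2 * sqrt(ci * co))
  as.numeric(b$rho_d / pi + spec)
}

#' Contrast-gloss values along a specular-reflectance grid
#'
#' Convenience wrapper used by the gloss-contrast (GC) task: maps each
#' `rho_s` on a grid to the contrast gloss `c` at fixed diffuse
#' reflectance.
#'
#' @param rho_s_grid numeric vector of specular energies.
#' @param rho_d diffuse reflectance (default 0.416, the GC task value).
#' @return Numeric vector of contrast-gloss values, same length as the grid.
#' @export
contrast_gloss_grid <- function(rho_s_grid, rho_d = 0.416) {
  vapply(rho_s_grid, function(rs)
    ward_to_perceptual(ward_brdf(rho_d, rs, alpha = 0.06))$c, numeric(1))
}
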