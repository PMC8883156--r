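#' Scene specification for the proxy renderer
#'
#' @param geometry a [geometry_spec()] (or object index 1-5, expanded via
#'   [geometry_preset()]).
#' @param illumination_id illumination proxy index 1-6.
#' @param pose_deg in-plane rotation of the object, a multiple of 36
#'   degrees (five poses, 0 to 144, are used under illumination
#'   condition 1).
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(geometry, illumination_id = 1L, pose_deg = 0) {
  if (is.numeric(geometry) && length(geometry) == 1)
    geometry <- geometry_preset(geometry)
  stopifnot(inherits(geometry, "geometry_spec"), illumination_id %in% 1:6)
  if (pose_deg %% 36 != 0)
    stop("pose_deg must be a multiple of 36 degrees")
  structure(list(geometry = geometry,
                 illumination_id = as.integer(illumination_id),
                 pose_deg = pose_deg %% 360),
            class = "scene_spec")
}

# --- shading primitives (all in linear RGB, view direction +z) ----------

# Ward specular term per pixel for one directional light; returns the
# outgoing radiance contribution (BRDF_spec * cos(theta_i)) as a scalar map
ward_spec_layer <- function(hf, light, rho_s, alpha) {
  l <- light$dir
  ci <- hf$nx * l[1] + hf$ny * l[2] + hf$nz * l[3]  # cos incidence vs normal
  co <- hf$nz                                        # view along +z
  # half vector of light and view directions
  hx <- l[1]; hy <- l[2]; hz <- l[3] + 1
  hn <- sqrt(hx^2 + hy^2 + hz^2)
  cosd <- (hf$nx * hx + hf$ny * hy + hf$nz * hz) / hn
  ok <- hf$mask & ci > 1e-6 & co > 1e-6 & cosd > 1e-6
  t2 <- (1 - cosd^2) / pmax(cosd^2, 1e-12)
  spec <- rho_s * exp(-t2 / alpha^2) / (4 * pi * alpha^2 * sqrt(pmax(ci * co, 1e-12)))
  out <- spec * ci
  out[!ok] <- 0
  out
}

# Lambertian shading map (scalar; multiply by albedo rgb per channel)
diffuse_layer <- function(hf, lights) {
  dl <- vector("list", 3)
  for (ch in 1:3) dl[[ch]] <- matrix(0, nrow(hf$h), ncol(hf$h))
  for (light in lights) {
    ci <- pmax(hf$nx * light$dir[1] + hf$ny * light$dir[2] +
                 hf$nz * light$dir[3], 0)
    for (ch in 1:3) dl[[ch]] <- dl[[ch]] + ci * light$rgb[ch] / pi
  }
  dl
}

# periodic Gaussian blur via FFT (wrap-around; the object sits well inside
# the frame so wrap effects are negligible)
gauss_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0.01) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  fx <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  fy <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1) / m
  gx <- exp(-2 * (pi * sigma_px * fx)^2)
  gy <- exp(-2 * (pi * sigma_px * fy)^2)
  Re(stats::fft(stats::fft(mat) * outer(gx, gy), inverse = TRUE)) / (n * m)
}

# background gradient (linear rgb), vertical interpolation
background_rgb <- function(proxy, n) {
  tgrid <- matrix(seq(0, 1, length.out = n), n, n, byrow = TRUE)
  lapply(1:3, function(ch)
    proxy$bg_top[ch] * (1 - tgrid) + proxy$bg_bottom[ch] * tgrid)
}

# material shading profiles used by the six dimensions
material_layers <- function(material, hf, proxy, size) {
  lights <- proxy$lights
  amb <- proxy$ambient
  dl <- diffuse_layer(hf, lights)
  zero <- matrix(0, size, size)
  shade <- function(albedo, rho_s, alpha, spec_rgb = c(1, 1, 1),
                    blur_alpha = NULL) {
    spec <- zero
    for (light in lights)
      spec <- spec + ward_spec_layer(hf, light,
                                     rho_s, if (is.null(blur_alpha)) alpha
                                            else 0.02) *
        mean(light$rgb)
    if (!is.null(blur_alpha))  # DOI realized as highlight blur
      spec <- gauss_blur(spec, sigma_px = size * blur_alpha * 0.5)
    diff <- lapply(1:3, function(ch)
      albedo[ch] * (dl[[ch]] + amb[ch] / pi))
    rgb <- lapply(1:3, function(ch) diff[[ch]] + spec_rgb[ch] * spec)
    list(rgb = rgb, spec = spec, diff = diff)
  }
  v <- material$value
  switch(material$dimension,
    GC = shade(rep(0.416, 3), rho_s = v, alpha = 0.06),
    GD = shade(rep(0.416, 3), rho_s = 0.06, alpha = 1 - v,
               blur_alpha = 1 - v),
    GP = shade(rep(0.416, 3),
               rho_s = (0.067 + 0.208^(1 / 3))^3 - 0.208,
               alpha = 1 - v, blur_alpha = 1 - v),
    OT = {
      surf <- shade(c(0.90, 0.88, 0.82), rho_s = 0.08, alpha = 0.03)
      transmit <- exp(-4 * v * hf$thickness)  # density scale v
      bg <- background_rgb(proxy, size)
      rgb <- lapply(1:3, function(ch)
        surf$spec * 1 +
          (1 - transmit) * surf$diff[[ch]] +
          transmit * (0.6 * proxy$backlight[ch] + 0.4 * bg[[ch]]))
      list(rgb = rgb, spec = surf$spec, diff = surf$diff)
    },
    MP = {
      gold <- shade(c(0.25, 0.18, 0.05), rho_s = 0.35, alpha = 0.12,
                    spec_rgb = c(1.0, 0.72, 0.30))
      plastic <- shade(c(0.75, 0.62, 0.12), rho_s = 0.06, alpha = 0.04)
      rgb <- lapply(1:3, function(ch)
        (1 - v) * gold$rgb[[ch]] + v * plastic$rgb[[ch]])
      list(rgb = rgb,
           spec = (1 - v) * gold$spec + v * plastic$spec,
           diff = lapply(1:3, function(ch)
             (1 - v) * gold$diff[[ch]] + v * plastic$diff[[ch]]))
    },
    MG = {
      silver <- shade(c(0.06, 0.06, 0.07), rho_s = 0.75, alpha = 0.08,
                      spec_rgb = c(0.98, 0.98, 1.0))
      bg <- background_rgb(proxy, size)
      gspec <- shade(c(0.02, 0.02, 0.02), rho_s = 0.10, alpha = 0.02)
      # glass: background transmitted with a normal-dependent offset
      glass_rgb <- lapply(1:3, function(ch)
        0.85 * bg[[ch]] * (0.6 + 0.4 * hf$nz) + gspec$rgb[[ch]])
      rgb <- lapply(1:3, function(ch)
        (1 - v) * silver$rgb[[ch]] + v * glass_rgb[[ch]])
      list(rgb = rgb,
           spec = (1 - v) * silver$spec + v * gspec$spec,
           diff = lapply(1:3, function(ch)
             (1 - v) * silver$diff[[ch]] + v * 0.85 * bg[[ch]]))
    })
}

# linear [0,1] -> 8-bit sRGB-style gamma 2.2 encoding
encode_8bit <- function(rgb_list, size) {
  img <- array(0L, dim = c(size, size, 3))
  for (ch in 1:3) {
    v <- pmin(pmax(rgb_list[[ch]], 0), 1)^(1 / 2.2)
    img[, , ch] <- as.integer(round(v * 255))
  }
  img
}

#' Render a procedural object image
#'
#' Proxy renderer for the stimulus corpus: a diffuse term shades the
#' height-field normals with the illumination proxy's directional lights,
#' a specular term evaluates the Ward lobe against those lights, DOI
#' manipulations blur the highlight layer with a kernel width monotone in
#' `alpha = 1 - d`, translucency attenuates a backlight/background term
#' with optical density proportional to the scale parameter, and the
#' gold-plastic / silver-glass morphs are per-pixel linear blends of the
#' two endpoint shading models. Output is deterministic given (scene,
#' material).
#'
#' @param scene a [scene_spec()].
#' @param material a [material_spec()].
#' @param size image side in pixels (>= 128).
#' @param layers if `TRUE`, also return the linear-light specular and
#'   diffuse layers and the object mask.
#' @return An integer array `size x size x 3` of 8-bit sRGB values
#'   (gamma 2.2), or a list if `layers = TRUE`.
#' @export
render_object <- function(scene, material, size = 256, layers = FALSE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(material, "material_spec"))
  if (size < 128) stop("size must be at least 128 pixels")
  if (material$dimension == "GP" && material$inconsistent)
    return(make_inconsistent_highlights(scene, material$value,
                                        seed = derive_seed(
                                          scene$geometry$seed, "gp",
                                          scene$pose_deg),
                                        size = size, layers = layers))
  proxy <- illum_proxy(scene$illumination_id)
  hf <- height_field(scene$geometry, size, scene$pose_deg)
  lay <- material_layers(material, hf, proxy, size)
  bg <- background_rgb(proxy, size)
  rgb <- lapply(1:3, function(ch) {
    out <- bg[[ch]]
    out[hf$mask] <- lay$rgb[[ch]][hf$mask]
    out
  })
  img <- encode_8bit(rgb, size)
  if (layers)
    list(image = img, rgb_linear = rgb, spec = lay$spec, diff = lay$diff,
         mask = hf$mask)
  else img
}

# bilinear sample of a matrix at fractional (row, col) positions
bilinear_sample <- function(mat, r, c) {
  n <- nrow(mat); m <- ncol(mat)
  r <- pmin(pmax(r, 1), n); c <- pmin(pmax(c, 1), m)
  r0 <- pmin(floor(r), n - 1); c0 <- pmin(floor(c), m - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
}

# exact per-channel histogram matching: the output pixel multiset equals
# the reference multiset (rank-based assignment; ties broken by index)
match_histogram <- function(img, ref) {
  out <- img
  for (ch in 1:3) {
    a <- as.vector(img[, , ch]); b <- sort(as.vector(ref[, , ch]))
    out[, , ch] <- array(b[rank(a, ties.method = "first")], dim(img[, , 1]))
  }
  out
}

#' Render a highlight-inconsistent ("painted") object image
#'
#' Two-pass construction mirroring the glossy-versus-painted stimuli: the
#' specular-only layer is rendered first, re-mapped onto the shape by a
#' polar (spherical-style) mapping with a seeded random rotation/offset
#' and tiling, and added to the diffuse-only render, so highlight
#' positions are inconsistent with the diffuse shading. The result's
#' per-channel color histogram is then matched exactly to the consistent
#' glossy render's histogram, removing pixel-histogram cues.
#'
#' @param scene a [scene_spec()].
#' @param d DOI parameter on the GP grid.
#' @param seed integer seed for the random mapping offset.
#' @param size image side in pixels.
#' @param repeat_count tiling factor of the highlight texture in the
#'   angular coordinate (configurable; default 2).
#' @param identity_mapping if `TRUE`, skip the random offset and tiling
#'   (degenerate case: reproduces the consistent image up to
#'   quantization).
#' @param layers if `TRUE`, return the layer decomposition as in
#'   [render_object()].
#' @return 8-bit integer image array (or list if `layers = TRUE`).
#' @export
make_inconsistent_highlights <- function(scene, d, seed, size = 256,
                                         repeat_count = 2,
                                         identity_mapping = FALSE,
                                         layers = FALSE) {
  mat <- material_spec("GP", d)
  proxy <- illum_proxy(scene$illumination_id)
  hf <- height_field(scene$geometry, size, scene$pose_deg)
  lay <- material_layers(mat, hf, proxy, size)
  bg <- background_rgb(proxy, size)
  # consistent reference render
  cons <- lapply(1:3, function(ch) {
    out <- bg[[ch]]
    out[hf$mask] <- lay$rgb[[ch]][hf$mask]
    out
  })
  cons_img <- encode_8bit(cons, size)
  # remap the specular layer in polar coordinates over the object disk
  if (identity_mapping) {
    spec2 <- lay$spec
  } else {
    s <- seq(-1, 1, length.out = size)
    x <- matrix(s, size, size); y <- matrix(s, size, size, byrow = TRUE)
    rr <- sqrt(x^2 + y^2); ang <- atan2(y, x)
    off <- with_seed(seed, stats::runif(2, c(0.5, 0.05), c(2 * pi - 0.5, 0.25)))
    ang2 <- (ang * repeat_count + off[1]) %% (2 * pi)
    ang2[ang2 > pi] <- ang2[ang2 > pi] - 2 * pi
    rr2 <- (rr + off[2]) %% 1
    xs <- rr2 * cos(ang2); ys <- rr2 * sin(ang2)
    rows <- (xs + 1) / 2 * (size - 1) + 1
    cols <- (ys + 1) / 2 * (size - 1) + 1
    spec2 <- matrix(bilinear_sample(lay$spec, as.vector(rows),
                                    as.vector(cols)), size, size)
    spec2[!hf$mask] <- 0
  }
  incons <- lapply(1:3, function(ch) {
    out <- bg[[ch]]
    obj <- lay$diff[[ch]] + spec2  # diffuse shading + remapped highlights
    out[hf$mask] <- obj[hf$mask]
    out
  })
  img <- match_histogram(encode_8bit(incons, size), cons_img)
  if (layers)
    list(image = img, rgb_linear = incons, spec = spec2, diff = lay$diff,
         mask = hf$mask, consistent_image = cons_img)
  else img
}
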