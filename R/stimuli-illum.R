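#' Parametric illumination proxies
#'
#' Six illumination environments are emulated by parametric mixtures of
#' directional lights plus ambient light, with distinct color temperatures,
#' contrasts and backgrounds. Proxies 1-3 are mutually similar (overcast
#' daylight variants; used together under illumination condition 2 and
#' singly under condition 1), proxies 4-6 are mutually dissimilar (warm
#' tungsten, cool interior, high-contrast top light; used together under
#' condition 3).
#'
#' @param id proxy index 1-6.
#' @return List of class `illum_proxy`: `lights` (list of `dir` unit
#'   vector and `rgb` intensity), `ambient` rgb, `backlight` rgb (used by
#'   the translucency proxy), `bg_top`/`bg_bottom` linear background
#'   colors.
#' @export
illum_proxy <- function(id) {
  stopifnot(id %in% 1:6)
  unitv <- function(v) v / sqrt(sum(v^2))
  L <- function(dir, rgb) list(dir = unitv(dir), rgb = rgb)
  proxies <- list(
    # 1-3: overcast daylight, slight variations (similar set)
    list(lights = list(L(c(0.35, 0.45, 0.82), c(0.95, 0.97, 1.00)),
                       L(c(-0.5, 0.2, 0.84), 0.35 * c(0.9, 0.95, 1.05))),
         ambient = c(0.32, 0.33, 0.36), backlight = c(0.75, 0.78, 0.85),
         bg_top = c(0.50, 0.53, 0.58), bg_bottom = c(0.28, 0.27, 0.26)),
    list(lights = list(L(c(0.30, 0.50, 0.81), c(0.92, 0.95, 1.02)),
                       L(c(-0.45, 0.15, 0.88), 0.32 * c(0.95, 0.97, 1.0))),
         ambient = c(0.30, 0.32, 0.35), backlight = c(0.72, 0.76, 0.84),
         bg_top = c(0.47, 0.51, 0.57), bg_bottom = c(0.27, 0.27, 0.27)),
    list(lights = list(L(c(0.42, 0.40, 0.81), c(0.97, 0.98, 0.97)),
                       L(c(-0.55, 0.25, 0.80), 0.38 * c(0.88, 0.93, 1.04))),
         ambient = c(0.33, 0.34, 0.36), backlight = c(0.77, 0.79, 0.84),
         bg_top = c(0.52, 0.54, 0.57), bg_bottom = c(0.29, 0.28, 0.26)),
    # 4: warm tungsten evening light, strong from the left
    list(lights = list(L(c(-0.75, 0.25, 0.61), 1.5 * c(1.00, 0.62, 0.30)),
                       L(c(0.4, -0.2, 0.89), 0.15 * c(1.0, 0.8, 0.6))),
         ambient = c(0.16, 0.10, 0.07), backlight = c(0.9, 0.55, 0.25),
         bg_top = c(0.30, 0.17, 0.09), bg_bottom = c(0.12, 0.07, 0.05)),
    # 5: cool dim interior, two soft lights
    list(lights = list(L(c(0.2, 0.6, 0.77), 0.55 * c(0.70, 0.82, 1.05)),
                       L(c(-0.3, -0.4, 0.87), 0.35 * c(0.65, 0.78, 1.0))),
         ambient = c(0.18, 0.22, 0.30), backlight = c(0.45, 0.55, 0.75),
         bg_top = c(0.20, 0.25, 0.34), bg_bottom = c(0.10, 0.12, 0.18)),
    # 6: high-contrast near-vertical key light
    list(lights = list(L(c(0.05, 0.95, 0.31), 2.0 * c(1.00, 0.98, 0.92)),
                       L(c(0.0, -0.5, 0.87), 0.08 * c(0.9, 0.9, 1.0))),
         ambient = c(0.08, 0.08, 0.09), backlight = c(0.95, 0.93, 0.88),
         bg_top = c(0.55, 0.54, 0.50), bg_bottom = c(0.06, 0.06, 0.07)))
  structure(c(proxies[[id]], list(id = id)), class = "illum_proxy")
}

# the proxy ids shown together under each illumination condition
illum_condition_proxies <- function(illumination_condition) {
  switch(as.character(illumination_condition),
         "1" = 1L, "2" = c(1L, 2L, 3L), "3" = c(4L, 5L, 6L),
         stop("illumination_condition must be 1, 2 or 3"))
}
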