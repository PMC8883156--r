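# ---- complex steerable pyramid (frequency domain, no subsampling) ------

# raised-cosine lowpass: 1 below cutoff/2, 0 above cutoff, log-radial ramp
.rc_lowpass <- function(r, cutoff) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r <= cutoff / 2] <- 1
  mid <- r > cutoff / 2 & r < cutoff
  out[mid] <- cos((pi / 2) * log2(2 * r[mid] / cutoff))
  out
}

# filter bank for an n x m plane: radial bands A[[s]] (s = 1 finest),
# cumulative lowpasses L[[s]], highpass H0, orientation windows G[[k]]
csp_filters <- function(n, m, n_scales = 4, n_orientations = 4) {
  fx <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  fy <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1) / m
  FX <- matrix(fx, n, m) * 2 * pi
  FY <- matrix(fy, n, m, byrow = TRUE) * 2 * pi
  r <- sqrt(FX^2 + FY^2)
  theta <- atan2(FY, FX)
  L <- vector("list", n_scales)
  Lprev <- .rc_lowpass(r, pi)          # L0: cutoff at Nyquist
  H0sq <- pmax(1 - Lprev^2, 0)
  A <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    Ls <- .rc_lowpass(r, pi / 2^s)
    A[[s]] <- sqrt(pmax(Lprev^2 - Ls^2, 0))
    L[[s]] <- Ls
    Lprev <- Ls
  }
  K <- n_orientations
  G <- vector("list", K)
  for (k in seq_len(K)) {
    th <- (k - 1) * pi / K
    dth <- atan2(sin(theta - th), cos(theta - th))
    Gk <- matrix(0, n, m)
    win <- abs(dth) < pi / 2          # single-sided: analytic subband
    Gk[win] <- cos(dth[win])^(K - 1)
    G[[k]] <- Gk
  }
  list(A = A, L = L, H0 = sqrt(H0sq), G = G)
}

.moments <- function(v) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 < 1e-24)  # constant input: variance-normalized statistics are 0
    return(c(mean = mu, sd = 0, skew = 0, kurt = 0))
  c(mean = mu, sd = sqrt(s2),
    skew = mean((v - mu)^3) / s2^1.5,
    kurt = mean((v - mu)^4) / s2^2)
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

# circular autocorrelation of a matrix at the four nearest lag offsets,
# normalized by the variance; 0 for a constant plane
.acorr_near <- function(mat) {
  mu <- mean(mat)
  v <- mat - mu
  pw <- sum(v^2)
  if (pw < 1e-20) return(0)
  ac <- Re(stats::fft(Mod(stats::fft(v))^2, inverse = TRUE)) /
    (nrow(mat) * ncol(mat))
  n <- nrow(mat)
  mean(c(ac[2, 1], ac[1, 2], ac[2, 2], ac[n, 2])) / pw
}

#' Steerable-pyramid texture statistics of a single image plane
#'
#' Computes the texture-statistics families used as intermediate visual
#' features: marginal moments of the plane (mean, SD, skewness,
#' kurtosis), the highpass-residual variance, near-lag autocorrelation of
#' the cumulative lowpass at each scale, subband magnitude means from a
#' complex steerable pyramid (`n_scales` x `n_orientations`, frequency
#' domain, circular boundary, no subsampling), magnitude correlations
#' across orientations within each scale and across adjacent scales, and
#' the skewness/kurtosis of the lowpass reconstruction at each scale.
#' Variance-normalized statistics of a constant plane are defined as 0.
#'
#' @param plane numeric matrix (>= 32 x 32, finite values).
#' @param n_scales,n_orientations pyramid size (defaults 4 and 4).
#' @return Named numeric vector of class `ps_statistics` (40 entries for
#'   the default pyramid; the 32-entry compressed set is selected by
#'   [reduce_features()] via [ps_registry_names()]).
#' @export
compute_ps_statistics <- function(plane, n_scales = 4, n_orientations = 4) {
  stopifnot(is.matrix(plane), nrow(plane) >= 32, ncol(plane) >= 32)
  if (!all(is.finite(plane))) stop("plane contains non-finite values")
  flt <- csp_filters(nrow(plane), ncol(plane), n_scales, n_orientations)
  Fp <- stats::fft(plane)
  npix <- length(plane)
  out <- c(.moments(as.vector(plane)))
  hp <- Re(stats::fft(Fp * flt$H0, inverse = TRUE)) / npix
  out <- c(out, hp_var = stats::var(as.vector(hp)))
  mags <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    mags[[s]] <- lapply(seq_len(n_orientations), function(k) {
      b <- stats::fft(Fp * (flt$A[[s]] * flt$G[[k]]), inverse = TRUE) / npix
      Mod(b)
    })
    lp <- Re(stats::fft(Fp * flt$L[[s]], inverse = TRUE)) / npix
    mom <- .moments(as.vector(lp))
    out <- c(out,
             stats::setNames(.acorr_near(lp), sprintf("acorr_s%d", s)),
             stats::setNames(mom["skew"], sprintf("lp_skew_s%d", s)),
             stats::setNames(mom["kurt"], sprintf("lp_kurt_s%d", s)))
  }
  for (s in seq_len(n_scales)) for (k in seq_len(n_orientations))
    out <- c(out, stats::setNames(mean(mags[[s]][[k]]),
                                  sprintf("mag_s%d_o%d", s, k)))
  for (s in seq_len(n_scales)) {
    prs <- utils::combn(n_orientations, 2)
    cors <- vapply(seq_len(ncol(prs)), function(j)
      .safe_cor(as.vector(mags[[s]][[prs[1, j]]]),
                as.vector(mags[[s]][[prs[2, j]]])), numeric(1))
    out <- c(out, stats::setNames(mean(cors), sprintf("xori_s%d", s)))
  }
  for (s in seq_len(n_scales - 1)) {
    cors <- vapply(seq_len(n_orientations), function(k)
      .safe_cor(as.vector(mags[[s]][[k]]),
                as.vector(mags[[s + 1]][[k]])), numeric(1))
    out <- c(out, stats::setNames(mean(cors), sprintf("xscl_s%d%d", s, s + 1)))
  }
  structure(out, class = c("ps_statistics", "numeric"))
}

#' Names of the 32-parameter compressed statistics set (per channel)
#'
#' The feature registry behind the per-channel reduction to 32
#' parameters: 4 marginal moments, 1 highpass variance, 4 lowpass
#' autocorrelation summaries (one per scale), 16 subband magnitude means
#' (scale x orientation), 4 within-scale cross-orientation magnitude
#' correlations and 3 adjacent-scale magnitude correlations. Swapping in
#' an alternative reduction only requires replacing this registry.
#'
#' @param n_scales,n_orientations pyramid size.
#' @return Character vector of length 32 (for the default pyramid).
#' @export
ps_registry_names <- function(n_scales = 4, n_orientations = 4) {
  c("mean", "sd", "skew", "kurt", "hp_var",
    sprintf("acorr_s%d", seq_len(n_scales)),
    as.vector(t(outer(seq_len(n_scales), seq_len(n_orientations),
                      function(s, k) sprintf("mag_s%d_o%d", s, k)))),
    sprintf("xori_s%d", seq_len(n_scales)),
    sprintf("xscl_s%d%d", seq_len(n_scales - 1), 2:n_scales))
}

#' Reduce per-channel statistics to a named feature vector
#'
#' Five variants mirror the five regression conditions: `color_means`
#' (3 = L*/a*/b* means), `color_stats` (12 = mean/SD/skewness/kurtosis
#' per channel), `ps_gray` (32 compressed statistics of L*),
#' `ps_gray_plus_color` (the union of `ps_gray` and `color_stats`; its
#' length is reported, not fixed), and `ps_color` (96 = 32 per channel).
#'
#' @param stats_lab list with elements `L`, `a`, `b`, each a
#'   [compute_ps_statistics()] vector.
#' @param variant one of `"color_means"`, `"color_stats"`, `"ps_gray"`,
#'   `"ps_gray_plus_color"`, `"ps_color"`.
#' @return Named numeric vector (3, 12, 32, 44 or 96 entries).
#' @export
reduce_features <- function(stats_lab,
                            variant = c("ps_color", "ps_gray",
                                        "ps_gray_plus_color",
                                        "color_stats", "color_means")) {
  variant <- match.arg(variant)
  stopifnot(all(c("L", "a", "b") %in% names(stats_lab)))
  reg <- ps_registry_names()
  missing_stats <- setdiff(reg, names(stats_lab$L))
  if (length(missing_stats))
    stop("statistics do not match the registry (wrong pyramid size?): ",
         paste(utils::head(missing_stats, 3), collapse = ", "))
  pick <- function(ch, keys, prefix)
    stats::setNames(as.numeric(stats_lab[[ch]][keys]),
                    paste(prefix, ch, keys, sep = "_"))
  marg <- c("mean", "sd", "skew", "kurt")
  out <- switch(variant,
    color_means = c(pick("L", "mean", "px"), pick("a", "mean", "px"),
                    pick("b", "mean", "px")),
    color_stats = c(pick("L", marg, "px"), pick("a", marg, "px"),
                    pick("b", marg, "px")),
    ps_gray = pick("L", reg, "ps"),
    ps_gray_plus_color = c(pick("L", reg, "ps"),
                           pick("L", marg, "px"), pick("a", marg, "px"),
                           pick("b", marg, "px")),
    ps_color = c(pick("L", reg, "ps"), pick("a", reg, "ps"),
                 pick("b", reg, "ps")))
  if (variant == "ps_gray_plus_color")
    message(sprintf("ps_gray_plus_color variant has %d parameters",
                    length(out)))
  out
}

#' Feature vector of one stimulus image
#'
#' Full per-image pipeline: center-crop to 128 x 128, convert to CIE
#' L*a*b* against the condition's diffuse-white point, compute the
#' steerable-pyramid statistics of each channel, and reduce to the
#' requested variant.
#'
#' @param img 8-bit integer image array.
#' @param white_point XYZ of the scene's diffuse white.
#' @param variant feature variant (see [reduce_features()]).
#' @param crop crop side in pixels (default 128).
#' @return Named numeric feature vector.
#' @export
image_features <- function(img, white_point, variant = "ps_color",
                           crop = 128) {
  lab <- rgb_to_lab(center_crop(img, crop), white_point)
  stats_lab <- list(L = compute_ps_statistics(lab$L),
                    a = compute_ps_statistics(lab$a),
                    b = compute_ps_statistics(lab$b))
  reduce_features(stats_lab, variant)
}

#' Corpus-wide feature standardization
#'
#' @param features numeric matrix, rows = images, named columns.
#' @return List with `center`, `scale` and `keep` (features whose corpus
#'   SD is positive; constant features are dropped with a warning).
#' @export
corpus_feature_scaling <- function(features) {
  stopifnot(is.matrix(features))
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  keep <- scl > 1e-12
  if (any(!keep))
    warning("dropping constant features: ",
            paste(colnames(features)[!keep], collapse = ", "))
  list(center = ctr[keep], scale = scl[keep], keep = keep)
}

#' Mean pairwise feature distance of a stimulus set
#'
#' Mean over all unordered image pairs of the Euclidean distance between
#' feature vectors, after per-feature z-scoring against the full corpus
#' (so heterogeneous statistics contribute on a common scale). Zero for
#' a set of identical images.
#'
#' @param features feature matrix of the condition's images (rows).
#' @param scaling a [corpus_feature_scaling()] result; if `NULL`, the
#'   supplied matrix is its own corpus.
#' @return Scalar mean pairwise distance (>= 0).
#' @export
mean_feature_distance <- function(features, scaling = NULL) {
  stopifnot(is.matrix(features))
  if (nrow(features) < 2) stop("need at least 2 images")
  if (is.null(scaling)) scaling <- corpus_feature_scaling(features)
  z <- sweep(sweep(features[, names(scaling$center), drop = FALSE], 2,
                   scaling$center), 2, scaling$scale, "/")
  mean(stats::dist(z))
}
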