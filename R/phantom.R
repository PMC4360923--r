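#' Specification of a brain-like test phantom
#'
#' The phantom is a deterministic piecewise-constant volume: a head-shaped
#' ellipsoid containing an outer rim tissue and three interior tissue classes
#' carved out by a smooth seeded random field, with exact-zero background
#' outside the head. The brightest-tissue intensity is `t` = 150, 250 or 255
#' for T1-, T2- and PD-weighted contrast respectively, matching the
#' convention that percent noise levels are defined relative to `t`.
#'
#' @param shape Integer length-3 voxel extents (default 64^3); every axis
#'   must be at least 16.
#' @param modality One of `"T1"`, `"T2"`, `"PD"`; selects the default tissue
#'   intensity table.
#' @param tissue_intensities Optional named numeric vector overriding the
#'   default table; must be non-negative with maximum equal to the modality's
#'   `t`. Names `rim`, `csf`, `gray`, `white` are used.
#' @param geometry_seed Integer seed for the interior tissue field.
#' @return A list of class `phantom_spec` (with the derived `t`).
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         modality = c("T1", "T2", "PD"),
                         tissue_intensities = NULL, geometry_seed = 1L) {
  modality <- match.arg(modality)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape too small for the phantom geometry (need >= 16 per axis)")
  t <- c(T1 = 150, T2 = 250, PD = 255)[[modality]]
  defaults <- switch(modality,
    T1 = c(csf = 37, gray = 105, rim = 120, white = 150),
    T2 = c(white = 62, gray = 110, rim = 140, csf = 250),
    PD = c(csf = 130, rim = 150, white = 180, gray = 255))
  ti <- if (is.null(tissue_intensities)) defaults else tissue_intensities
  if (any(ti < 0) || any(ti > t) || max(ti) != t)
    stop("tissue intensities must lie in [0, t] with maximum exactly t = ", t)
  structure(list(shape = shape, modality = modality, t = t,
                 tissue_intensities = ti,
                 geometry_seed = as.integer(geometry_seed)),
            class = "phantom_spec")
}

#' Generate a piecewise-constant brain-like phantom
#'
#' @param spec A [phantom_spec()].
#' @return An `mr_volume`; zero outside the head ellipsoid (at least 25% of
#'   voxels), maximum intensity exactly `spec$t`, bitwise reproducible for a
#'   given `geometry_seed`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  # normalized coordinates in [-1, 1] per axis
  cx <- (seq_len(d[1L]) - (d[1L] + 1) / 2) / (d[1L] / 2)
  cy <- (seq_len(d[2L]) - (d[2L] + 1) / 2) / (d[2L] / 2)
  cz <- (seq_len(d[3L]) - (d[3L] + 1) / 2) / (d[3L] / 2)
  X <- array(rep(cx, times = d[2L] * d[3L]), d)
  Y <- array(rep(rep(cy, each = d[1L]), times = d[3L]), d)
  Z <- array(rep(cz, each = d[1L] * d[2L]), d)
  R2 <- (X / 0.82)^2 + (Y / 0.86)^2 + (Z / 0.80)^2
  head <- R2 <= 1
  inner <- R2 <= 0.78^2

  ti <- spec$tissue_intensities
  out <- array(0, d)
  out[head & !inner] <- ti[["rim"]]

  # smooth seeded field: superposition of random plane-wave cosines
  u <- with_seed(spec$geometry_seed, {
    acc <- array(0, d)
    for (w in 1:8) {
      fr <- runif(3, 0.5, 2.5)
      ph <- runif(3, 0, 2 * pi)
      amp <- runif(1, 0.5, 1)
      acc <- acc + amp * cos(pi * fr[1L] * X + ph[1L]) *
                         cos(pi * fr[2L] * Y + ph[2L]) *
                         cos(pi * fr[3L] * Z + ph[3L])
    }
    acc
  })
  ui <- u[inner]
  qs <- quantile(ui, c(0.22, 0.60))
  cls <- findInterval(ui, qs)  # 0 = csf, 1 = gray, 2 = white
  lv <- c(ti[["csf"]], ti[["gray"]], ti[["white"]])
  out[inner] <- lv[cls + 1L]
  # guarantee the brightest class is present even for degenerate fields
  if (max(out) < spec$t) out[inner][which.max(ui)] <- spec$t
  mr_volume(out)
}

#' Rician noise specification
#'
#' The per-channel noise standard deviation follows the percent convention
#' \eqn{\sigma = (p/100)\, t}, where `t` is the brightest-tissue intensity of
#' the ground-truth volume. The complex phase is fixed at 0.
#'
#' @param percent Noise level p in percent (typical study levels: 9, 13, 17,
#'   21); must be non-negative.
#' @param t Brightest-tissue intensity.
#' @param seed Integer seed for the two Gaussian noise fields.
#' @return A list of class `noise_spec` with derived `sigma`.
#' @export
noise_spec <- function(percent, t, seed = 1L) {
  if (!is.numeric(percent) || length(percent) != 1L || is.na(percent) ||
      percent < 0)
    stop("percent must be a single non-negative number")
  stopifnot(is.numeric(t), t > 0)
  structure(list(percent = percent, t = t, sigma = percent / 100 * t,
                 theta = 0, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt a clean volume with Rician noise
#'
#' Draws two independent standard-normal fields \eqn{g_1, g_2} from one
#' seeded stream (first field, then second) and returns
#' \eqn{\sqrt{(r + \sigma g_1)^2 + (\sigma g_2)^2}} voxelwise, i.e. the
#' magnitude of a complex signal with zero phase whose real and imaginary
#' channels carry independent Gaussian noise of standard deviation
#' \eqn{\sigma}.
#'
#' @param clean `mr_volume` of non-negative ground-truth intensities.
#' @param spec A [noise_spec()]; alternatively pass `percent` and `seed`
#'   directly and `t` defaults to `max(clean)`.
#' @param percent,seed,t Used when `spec` is missing.
#' @return Noisy `mr_volume`, non-negative everywhere; `percent = 0` returns
#'   the input unchanged.
#' @export
add_rician_noise <- function(clean, spec = NULL, percent = NULL, seed = 1L,
                             t = NULL) {
  clean <- as_mr_volume(clean)
  if (min(clean$data) < 0) stop("clean volume must be non-negative")
  if (is.null(spec)) {
    if (is.null(percent)) stop("provide a noise_spec or a percent level")
    if (is.null(t)) t <- max(clean$data)
    spec <- noise_spec(percent, t, seed)
  }
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$sigma == 0) return(clean)
  n <- length(clean$data)
  g <- with_seed(spec$seed, list(g1 = rnorm(n), g2 = rnorm(n)))
  noisy <- sqrt((as.vector(clean$data) + spec$sigma * g$g1)^2 +
                (spec$sigma * g$g2)^2)
  mr_volume(array(noisy, dim(clean$data)), clean$spacing)
}
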