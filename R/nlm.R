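#' Non-local means parameters
#'
#' @param patch_size Odd per-axis patch extent; default 5 (a 5x5x5 block),
#'   the usual choice for 1 mm isotropic brain MRI.
#' @param search_size Odd per-axis search-window extent; default 11
#'   (11x11x11). Must be at least `patch_size`.
#' @param h Filtering degree, in intensity units of the domain being
#'   filtered. Larger h smooths more; after variance stabilization the noise
#'   standard deviation is 1, so h is O(1) there.
#' @param patch_gaussian_a Standard deviation (voxels) of the Gaussian patch
#'   weighting kernel \eqn{G_a}; default 1. The kernel is normalized to sum
#'   to 1 over the patch, so patch distances are weighted mean squared
#'   differences.
#' @return A list of class `nlm_params`.
#' @export
nlm_params <- function(patch_size = 5L, search_size = 11L, h = NULL,
                       patch_gaussian_a = 1) {
  patch_size <- as.integer(patch_size)
  search_size <- as.integer(search_size)
  if (patch_size < 1L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 1")
  if (search_size < 1L || search_size %% 2L == 0L)
    stop("search_size must be odd and >= 1")
  if (patch_size > search_size)
    stop("patch_size must not exceed search_size")
  if (!is.null(h) && (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0))
    stop("h must be a single positive number")
  if (patch_gaussian_a <= 0) stop("patch_gaussian_a must be > 0")
  structure(list(patch_size = patch_size, search_size = search_size,
                 h = if (is.null(h)) NULL else as.numeric(h),
                 patch_gaussian_a = patch_gaussian_a),
            class = "nlm_params")
}

# 1D factor of the normalized separable Gaussian patch kernel G_a; the 3D
# kernel is the outer product of three of these and sums to 1 over the patch
.patch_kernel <- function(patch_size, a) {
  r <- (patch_size - 1L) %/% 2L
  g1 <- exp(-(-r:r)^2 / (2 * a^2))
  g1 / sum(g1)
}

#' Non-local means denoising with a separate guidance image
#'
#' Each output voxel is the weighted average of intensities of `transformed`
#' over the search window centred at that voxel. The weights decay
#' exponentially with the \eqn{G_a}-weighted squared patch distance scaled by
#' \eqn{h^2} — but the distances are computed on `presmoothed`, the
#' pre-smoothed guidance image, which is the pre-smoothed NLM (PSNLM) idea:
#' smoothing the guidance makes patch comparisons far less noisy while the
#' averaged intensities remain unbiased. Patches at borders use reflective
#' padding; the search window is clipped at borders and the weights
#' renormalized, so the output is a convex combination everywhere.
#'
#' @param transformed `mr_volume` whose intensities are averaged.
#' @param presmoothed `mr_volume` (same shape) from which patch distances are
#'   computed. Pass `transformed` itself for classic NLM.
#' @param params [nlm_params()] with `h` set.
#' @return Denoised `mr_volume`.
#' @export
psnlm_denoise <- function(transformed, presmoothed, params) {
  transformed <- as_mr_volume(transformed)
  presmoothed <- as_mr_volume(presmoothed)
  stopifnot(inherits(params, "nlm_params"))
  check_same_shape(transformed, presmoothed)
  if (is.null(params$h)) stop("nlm_params$h must be set for denoising")
  d <- dim(transformed$data)
  if (any(d < params$patch_size))
    stop("volume extents must be >= patch_size in every axis")
  pr <- (params$patch_size - 1L) %/% 2L
  sr <- (params$search_size - 1L) %/% 2L
  ga <- .patch_kernel(params$patch_size, params$patch_gaussian_a)
  out <- cpp_psnlm(as.vector(transformed$data), as.vector(presmoothed$data),
                   as.integer(d), pr, sr, params$h, ga)
  mr_volume(array(out, d), transformed$spacing)
}

#' Classic non-local means denoising
#'
#' Equivalent to [psnlm_denoise()] with the noisy volume as its own guidance
#' image (weights computed from the noisy data themselves).
#'
#' @param noisy `mr_volume` to denoise.
#' @inheritParams psnlm_denoise
#' @return Denoised `mr_volume`.
#' @export
nlm_denoise <- function(noisy, params) {
  noisy <- as_mr_volume(noisy)
  psnlm_denoise(noisy, noisy, params)
}
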