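#' Squared magnitude of a magnitude MR volume
#'
#' For a Rician-distributed magnitude \eqn{|z|} with true signal \eqn{r} and
#' per-channel noise standard deviation \eqn{\sigma},
#' \eqn{E|z|^2 = r^2 + 2\sigma^2}: the squared image carries an additive,
#' signal-independent noise bias of \eqn{2\sigma^2}. Squaring is therefore the
#' simplest transform that makes Rician noise tractable for filters designed
#' for additive noise.
#'
#' @param v An `mr_volume` with non-negative intensities.
#' @return An `mr_volume` holding the elementwise square.
#' @export
squared_magnitude <- function(v) {
  v <- as_mr_volume(v)
  if (min(v$data) < 0)
    stop("magnitude images are non-negative; found value ", min(v$data))
  mr_volume(v$data^2, v$spacing)
}

#' Estimate the Rician noise level from the image background
#'
#' In the zero-signal background of a magnitude image the squared intensities
#' have mean \eqn{\mu = 2\sigma^2}, so \eqn{\sigma = \sqrt{\mu/2}}. The mean
#' is the plain arithmetic mean over the mask, with no trimming.
#'
#' @param squared `mr_volume` of squared magnitudes (see
#'   [squared_magnitude()]).
#' @param background `mr_mask` marking zero-signal background voxels; must
#'   contain at least one `TRUE` voxel and match the volume's shape.
#' @return A `noise_estimate` object: list with `sigma`, `background_mean`
#'   (\eqn{\mu}) and `n_background`.
#' @export
estimate_sigma <- function(squared, background) {
  squared <- as_mr_volume(squared)
  background <- as_mr_mask(background)
  check_same_shape(squared, background)
  n <- sum(background$data)
  if (n < 1L) stop("empty background: mask has no TRUE voxels")
  mu <- mean(squared$data[background$data])
  structure(list(sigma = sqrt(mu / 2), background_mean = mu,
                 n_background = n),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.6g (background mean %.6g over %d voxels)\n",
              x$sigma, x$background_mean, x$n_background))
  invisible(x)
}

#' Remove the squared-magnitude noise bias
#'
#' Subtracts the \eqn{2\sigma^2} bias from a denoised squared-magnitude
#' volume, clamps negatives to zero (magnitudes are non-negative) and takes
#' the square root.
#'
#' @param denoised_squared `mr_volume` in the squared-magnitude domain.
#' @param sigma Noise standard deviation, \eqn{\sigma \ge 0}.
#' @return An `mr_volume` of unbiased magnitudes, everywhere \eqn{\ge 0}.
#' @export
unbias_squared <- function(denoised_squared, sigma) {
  v <- as_mr_volume(denoised_squared)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  mr_volume(sqrt(pmax(v$data - 2 * sigma^2, 0)), v$spacing)
}
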