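#' Background segmentation settings
#'
#' @param median_window Odd per-axis extent of the pre-segmentation median
#'   filter (default 3).
#' @param close_radius Radius in voxels of the ball structuring element used
#'   for the morphological close of the foreground (default 2).
#' @param histogram_bins Number of histogram bins for Otsu thresholding
#'   (default 256, matching 8-bit intensity quantization).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(median_window = 3L, close_radius = 2L,
                                histogram_bins = 256L) {
  median_window <- as.integer(median_window)
  if (median_window < 1L || median_window %% 2L == 0L)
    stop("median_window must be odd and >= 1")
  if (close_radius < 0L) stop("close_radius must be >= 0")
  if (histogram_bins < 2L) stop("histogram_bins must be >= 2")
  structure(list(median_window = median_window,
                 close_radius = as.integer(close_radius),
                 histogram_bins = as.integer(histogram_bins)),
            class = "segmentation_config")
}

#' Otsu threshold of a volume histogram
#'
#' Exhaustively searches the bin edges of the intensity histogram for the cut
#' maximizing the between-class variance \eqn{w_0 w_1 (\mu_0 - \mu_1)^2};
#' ties are broken towards the lowest threshold.
#'
#' @param v `mr_volume` (or 3D array) with at least two distinct values.
#' @param bins Number of histogram bins.
#' @return The threshold intensity (a bin edge). Voxels strictly above it
#'   form the bright (foreground) class.
#' @export
otsu_threshold <- function(v, bins = 256L) {
  v <- as_mr_volume(v)
  x <- as.vector(v$data)
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("degenerate histogram: volume is constant")
  bins <- as.integer(bins)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = bins)
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  w <- cumsum(cnt)
  s <- cumsum(cnt * mids)
  n <- w[bins]
  tot <- s[bins]
  # candidate cuts after bin b, b = 1..bins-1
  w0 <- w[-bins]
  s0 <- s[-bins]
  valid <- w0 > 0 & w0 < n
  mu0 <- s0 / w0
  mu1 <- (tot - s0) / (n - w0)
  bc <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  bc[!valid] <- -Inf
  b <- which.max(bc)  # first max = lowest threshold on ties
  breaks[b + 1L]
}

# ---- small 3D morphology toolkit (shift-based; masks are logical arrays) ----

# shift logical array along axis by one step, padding with `fill`
.shift1 <- function(m, axis, by, fill) {
  d <- dim(m)
  out <- array(fill, d)
  n <- d[axis]
  if (n <= 1L) return(out)
  src <- dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src <- if (by > 0) 1:(n - 1L) else 2:n
  idx_dst <- if (by > 0) 2:n else 1:(n - 1L)
  pick <- function(a, axis, idx) {
    args <- rep(list(TRUE), 3L)
    args[[axis]] <- idx
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  args <- rep(list(TRUE), 3L)
  args[[axis]] <- idx_dst
  out <- do.call(`[<-`, c(list(out), args, list(value = pick(m, axis, idx_src))))
  out
}

# shift by an arbitrary integer offset (repeated single shifts; offsets small)
.shiftn <- function(m, offset, fill) {
  for (ax in 1:3) {
    k <- offset[ax]
    while (k != 0L) {
      m <- .shift1(m, ax, sign(k), fill)
      k <- k - sign(k)
    }
  }
  m
}

.ball_offsets <- function(r) {
  if (r == 0L) return(matrix(0L, 1L, 3L))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

.dilate <- function(m, offsets) {
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offsets)))
    out <- out | .shiftn(m, offsets[i, ], FALSE)
  out
}

.erode <- function(m, offsets) !.dilate(!m, offsets)

.close_fg <- function(m, r) {
  if (r == 0L) return(m)
  off <- .ball_offsets(r)
  .erode(.dilate(m, off), off)
}

# fill cavities: background voxels not 6-connected to the border become
# foreground
.fill_holes <- function(fg) {
  bg <- !fg
  d <- dim(fg)
  seed <- array(FALSE, d)
  seed[c(1L, d[1L]), , ] <- TRUE
  seed[, c(1L, d[2L]), ] <- TRUE
  seed[, , c(1L, d[3L])] <- TRUE
  seed <- seed & bg
  off6 <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  repeat {
    grown <- (seed | .dilate(seed, off6)) & bg
    if (sum(grown) == sum(seed)) break
    seed <- grown
  }
  fg | (bg & !seed)
}

#' Extract the zero-signal background of a magnitude MR volume
#'
#' Runs the four-step procedure: median filtering, Otsu binarization (bright
#' class = head), morphological close of the foreground with a ball element,
#' and hole filling in full 3D 6-connectivity (so dark cavities enclosed by
#' tissue are counted as foreground, not background). The filled foreground
#' is finally dilated by `close_radius` as a safety margin — the median
#' filter nibbles about a voxel off the head boundary, and noise estimation
#' must stay clear of boundary voxels — and the returned mask is the
#' complement of that margin-padded foreground.
#'
#' @param v `mr_volume` with near-zero background (magnitude image).
#' @param config A [segmentation_config()].
#' @return An `mr_mask` where `TRUE` marks background voxels.
#' @export
extract_background <- function(v, config = segmentation_config()) {
  v <- as_mr_volume(v)
  stopifnot(inherits(config, "segmentation_config"))
  sm <- if (config$median_window > 1L) {
    array(cpp_median3d(v$data, dim(v$data), config$median_window), dim(v$data))
  } else v$data
  thr <- otsu_threshold(mr_volume(sm, v$spacing), config$histogram_bins)
  fg <- sm > thr
  fg <- .close_fg(fg, config$close_radius)
  fg <- .fill_holes(fg)
  if (config$close_radius > 0L)
    fg <- .dilate(fg, .ball_offsets(config$close_radius))
  mr_mask(!fg)
}
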