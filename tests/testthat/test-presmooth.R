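test_that("every pre-smoother leaves a constant volume unchanged", {
  v <- mr_volume(array(42, c(8, 8, 8)))
  for (m in c("gaussian", "median", "anisotropic", "identity")) {
    out <- presmooth(v, presmooth_config(m))
    expect_equal(out$data, v$data, tolerance = 1e-12, info = m)
  }
})

test_that("the Gaussian impulse response is the normalized kernel", {
  n <- 17
  v <- array(0, c(n, n, n))
  v[9, 9, 9] <- 1
  out <- presmooth(mr_volume(v), presmooth_config("gaussian",
                                                  gaussian_sigma = 1))
  expect_equal(sum(out$data), 1, tolerance = 1e-12)  # mass conservation
  k <- psnlm:::.gaussian_kernel1d(1)
  r <- (length(k) - 1) / 2
  expected <- outer(outer(k, k), k)
  got <- out$data[(9 - r):(9 + r), (9 - r):(9 + r), (9 - r):(9 + r)]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("the median filter removes a single-voxel outlier", {
  v <- array(10, c(7, 7, 7))
  v[4, 4, 4] <- 100
  out <- presmooth(mr_volume(v), presmooth_config("median",
                                                  median_window = 3))
  # explicit sort of the 27-voxel window centred on the outlier
  win <- sort(c(rep(10, 26), 100))
  expect_equal(out$data[4, 4, 4], win[14])
  expect_equal(out$data[4, 4, 4], 10)
})

test_that("median output values always come from the local input window", {
  set.seed(303)
  v <- array(sample(c(1, 2, 5, 9), 6^3, replace = TRUE), c(6, 6, 6))
  out <- presmooth(mr_volume(v), presmooth_config("median",
                                                  median_window = 3))
  expect_true(all(out$data %in% c(1, 2, 5, 9)))
})

test_that("Gaussian and diffusion smoothing conserve the volume mean", {
  set.seed(304)
  v <- array(runif(10^3, 0, 100), c(10, 10, 10))
  g <- presmooth(mr_volume(v), presmooth_config("gaussian",
                                                gaussian_sigma = 1.4))
  expect_equal(mean(g$data), mean(v), tolerance = 1e-8)
  a <- presmooth(mr_volume(v), presmooth_config("anisotropic",
                                                diffusion_iterations = 10))
  expect_equal(mean(a$data), mean(v), tolerance = 1e-8)
})

test_that("diffusion with huge kappa reduces to linear (heat) diffusion", {
  set.seed(305)
  v <- array(runif(8^3, 0, 10), c(8, 8, 8))
  out <- presmooth(mr_volume(v),
                   presmooth_config("anisotropic", diffusion_iterations = 3,
                                    diffusion_kappa = 1e8,
                                    diffusion_lambda = 0.1))
  # independent explicit heat steps with replicated-edge Laplacian
  lin <- v
  for (it in 1:3) {
    lap <- array(0, dim(lin))
    for (ax in 1:3) {
      lap <- lap + (psnlm:::.shift_rep(lin, ax, 1L) - lin) +
        (psnlm:::.shift_rep(lin, ax, -1L) - lin)
    }
    lin <- lin + 0.1 * lap
  }
  expect_equal(out$data, lin, tolerance = 1e-10)
})

test_that("invalid pre-smoothing settings are rejected", {
  expect_error(presmooth_config("gaussian", gaussian_sigma = 0), "> 0")
  expect_error(presmooth_config("median", median_window = 4), "odd")
  expect_error(presmooth_config("anisotropic", diffusion_lambda = 0.3),
               "1/6")
  expect_error(presmooth_config("wavelet"), "arg")
})
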