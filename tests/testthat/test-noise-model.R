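test_that("squared magnitude is the elementwise square and rejects negatives", {
  v <- mr_volume(array(c(2, 0, 3), c(3, 1, 1)))
  expect_equal(squared_magnitude(v)$data, array(c(4, 0, 9), c(3, 1, 1)))
  expect_error(squared_magnitude(mr_volume(array(-1, c(2, 2, 2)))),
               "non-negative")
})

test_that("the second moment of Rician samples is r^2 + 2 sigma^2", {
  # Monte-Carlo against the closed-form moment that the squared-magnitude
  # bias correction relies on
  set.seed(2001)
  n <- 1e6
  for (r in c(0, 50)) {
    z2 <- (r + 10 * rnorm(n))^2 + (10 * rnorm(n))^2
    expect_equal(mean(z2), r^2 + 200, tolerance = 0.01)
  }
})

test_that("sigma is recovered from the background mean of the squared image", {
  # mu = 200 over background -> sigma = 10, independent of foreground content
  d <- c(6, 6, 6)
  bg <- array(FALSE, d)
  bg[1:3, , ] <- TRUE
  sq <- array(999, d)
  sq[bg] <- 200
  est <- estimate_sigma(mr_volume(sq), mr_mask(bg))
  expect_equal(est$sigma, 10)
  expect_equal(est$background_mean, 200)
  expect_equal(est$n_background, sum(bg))

  # foreground invariance: scrambling non-background voxels changes nothing
  sq2 <- sq
  sq2[!bg] <- 12345
  expect_identical(estimate_sigma(mr_volume(sq2), mr_mask(bg))$sigma,
                   est$sigma)

  expect_error(estimate_sigma(mr_volume(sq), mr_mask(array(FALSE, d))),
               "empty background")
})

test_that("sigma estimation on simulated phantoms is accurate to 2%", {
  ph <- generate_phantom(phantom_spec(c(64, 64, 64), "T1"))
  noisy <- add_rician_noise(ph, percent = 9, seed = 31)
  est <- estimate_sigma(squared_magnitude(noisy), extract_background(noisy))
  expect_equal(est$sigma, 13.5, tolerance = 0.02)
})

test_that("bias correction subtracts 2 sigma^2, clamps, and takes the root", {
  v <- mr_volume(array(c(300, 100), c(2, 1, 1)))
  out <- unbias_squared(v, 10)
  expect_equal(out$data[1], 10)   # sqrt(300 - 200)
  expect_equal(out$data[2], 0)    # clamped below the bias
  expect_true(all(out$data >= 0))
  expect_error(unbias_squared(v, -1), "non-negative")

  # composition: unbias(square(r) + 2 sigma^2) == r exactly for clean r
  r <- array(abs(rnorm(27, 50, 20)), c(3, 3, 3))
  sq <- squared_magnitude(mr_volume(r))
  rec <- unbias_squared(mr_volume(sq$data + 2 * 49), 7)
  expect_equal(rec$data, r, tolerance = 1e-12)
})

test_that("bias correction recovers the true signal from sample moments", {
  set.seed(77)
  n <- 1e6
  for (r in c(20, 50)) {
    z2 <- (r + 10 * rnorm(n))^2 + (10 * rnorm(n))^2
    rec <- unbias_squared(mr_volume(array(mean(z2), c(1, 1, 1))), 10)$data[1]
    expect_equal(rec, r, tolerance = 0.01)
  }
  z2 <- (10 * rnorm(n))^2 + (10 * rnorm(n))^2
  rec0 <- unbias_squared(mr_volume(array(mean(z2), c(1, 1, 1))), 10)$data[1]
  expect_lt(rec0, 1)  # r = 0: clamp keeps the estimate at/near zero
})
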