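# one table shared across this file; construction is deterministic
vst_tab <- build_vst()

test_that("Rician moments match their closed-form limits", {
  m0 <- rician_moments(0)
  expect_equal(m0$mean, sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(m0$sd, sqrt(2 - pi / 2), tolerance = 1e-12)

  mbig <- rician_moments(100)
  expect_equal(mbig$sd, 1, tolerance = 1e-3)
  expect_equal(mbig$mean - 100, 0.005, tolerance = 1e-4)

  expect_error(rician_moments(-1), "non-negative")
})

test_that("Rician moments agree with Monte-Carlo sampling at nu = 1", {
  set.seed(5)
  n <- 1e7
  z <- sqrt((1 + rnorm(n))^2 + rnorm(n)^2)
  m <- rician_moments(1)
  expect_equal(m$mean, mean(z), tolerance = 1e-3)
  expect_equal(m$sd, sd(z), tolerance = 1e-3)
})

test_that("the constructed stabilizer is monotone with an affine tail", {
  expect_true(all(diff(vst_tab$f_values) > 0))
  # high-SNR regime: f(x) - x settles to a constant
  sel <- vst_tab$grid >= 50
  tail_dev <- vst_tab$f_values[sel] - vst_tab$grid[sel]
  expect_lt(max(tail_dev) - min(tail_dev), 1e-2)
})

test_that("the forward transform stabilizes the noise variance", {
  set.seed(6)
  n <- 2e5
  for (nu in c(0, 1, 4)) {
    z <- sqrt((nu + rnorm(n))^2 + rnorm(n)^2)
    fz <- forward_vst(mr_volume(array(z, c(length(z), 1, 1))), 1,
                      vst_tab)$data
    expect_gt(sd(fz), 0.9)
    expect_lt(sd(fz), 1.1)
  }
})

test_that("forward transform is an order-preserving elementwise map", {
  v <- mr_volume(array(42, c(3, 3, 3)))
  out <- forward_vst(v, 5, vst_tab)
  expect_equal(max(out$data) - min(out$data), 0)

  set.seed(8)
  x <- sort(runif(100, 0, 400))
  y <- forward_vst(mr_volume(array(x, c(100, 1, 1))), 15, vst_tab)$data
  expect_true(all(diff(as.vector(y)) >= 0))

  expect_error(forward_vst(v, 0, vst_tab), "positive")
  expect_error(forward_vst(v, 5, list()), "vst_table")
})

test_that("the exact-unbiased inverse undoes the filtered expectation", {
  # independent quadrature oracle for E[f(z) | nu]
  for (nu in c(2, 4, 8)) {
    ef <- efz_oracle(vst_tab, nu)
    rec <- inverse_vst(mr_volume(array(ef, c(1, 1, 1))), 1, vst_tab)$data[1]
    expect_equal(rec, nu, tolerance = 0.01)
  }
  # sigma scaling: same check at sigma = 15
  ef <- efz_oracle(vst_tab, 4)
  rec <- inverse_vst(mr_volume(array(ef, c(1, 1, 1))), 15, vst_tab)$data[1]
  expect_equal(rec, 60, tolerance = 0.01 * 15)
})

test_that("inverse maps sub-minimum values to zero and inverts the tail", {
  low <- mr_volume(array(0, c(2, 2, 2)))
  expect_equal(inverse_vst(low, 10, vst_tab)$data,
               array(0, c(2, 2, 2)))

  # noiseless high-SNR round trip at r = 100 sigma: the exact-unbiased
  # inverse targets noisy expectations, so a clean value comes back offset
  # by the Rician mean bias sigma^2/(2r) = 0.005 sigma; allow that plus a
  # little interpolation error
  sigma <- 3
  r <- mr_volume(array(300, c(2, 2, 2)))
  round_trip <- inverse_vst(forward_vst(r, sigma, vst_tab), sigma, vst_tab)
  expect_lt(abs(round_trip$data[1] - 300), 0.0055 * sigma)
})

test_that("VST tables serialize to JSON and restore exactly", {
  f <- tempfile(fileext = ".json")
  write_vst(vst_tab, f)
  r <- read_vst(f)
  expect_equal(r$f_values, vst_tab$f_values)
  expect_equal(r$inverse_grid, vst_tab$inverse_grid)
  v <- mr_volume(array(runif(8, 0, 100), c(2, 2, 2)))
  expect_equal(forward_vst(v, 7, r)$data, forward_vst(v, 7, vst_tab)$data)
})
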