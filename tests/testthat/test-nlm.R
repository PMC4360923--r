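test_that("NLM matches the brute-force all-pairs oracle", {
  set.seed(404)
  for (i in 1:3) {
    v <- array(runif(729), c(9, 9, 9))
    g <- array(runif(729), c(9, 9, 9))
    p <- nlm_params(patch_size = 5, search_size = 17, h = 0.8)
    expect_lt(max(abs(nlm_denoise(v, p)$data - nlm_oracle(v, v, 5, 0.8))),
              1e-10)
    expect_lt(max(abs(psnlm_denoise(v, g, p)$data - nlm_oracle(v, g, 5, 0.8))),
              1e-10)
  }
})

test_that("a constant volume is an exact fixed point", {
  v <- mr_volume(array(3.25, c(8, 8, 8)))
  out <- nlm_denoise(v, nlm_params(patch_size = 3, search_size = 7, h = 2))
  expect_equal(out$data, v$data, tolerance = 1e-14)
})

test_that("infinite h reduces NLM to the windowed mean", {
  set.seed(405)
  n <- 7
  v <- array(runif(n^3), c(n, n, n))
  out <- nlm_denoise(mr_volume(v),
                     nlm_params(patch_size = 3, search_size = 3, h = 1e6))
  box <- array(0, dim(v))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    box[i, j, k] <- mean(v[max(1, i - 1):min(n, i + 1),
                           max(1, j - 1):min(n, j + 1),
                           max(1, k - 1):min(n, k + 1)])
  expect_lt(max(abs(out$data - box)), 1e-6)
})

test_that("outputs are convex combinations over the search window", {
  set.seed(406)
  v <- array(runif(10^3, -5, 5), c(10, 10, 10))
  g <- array(runif(10^3), c(10, 10, 10))
  out <- psnlm_denoise(v, g, nlm_params(patch_size = 3, search_size = 5,
                                        h = 0.5))$data
  r <- 2
  for (idx in list(c(1, 1, 1), c(5, 6, 4), c(10, 10, 10))) {
    w <- v[max(1, idx[1] - r):min(10, idx[1] + r),
           max(1, idx[2] - r):min(10, idx[2] + r),
           max(1, idx[3] - r):min(10, idx[3] + r)]
    x <- out[idx[1], idx[2], idx[3]]
    expect_gte(x, min(w) - 1e-12)
    expect_lte(x, max(w) + 1e-12)
  }
})

test_that("axis flips commute with the filter", {
  set.seed(407)
  v <- array(runif(8^3), c(8, 8, 8))
  g <- array(runif(8^3), c(8, 8, 8))
  p <- nlm_params(patch_size = 3, search_size = 5, h = 0.7)
  flip1 <- function(a) a[rev(seq_len(dim(a)[1])), , ]
  straight <- psnlm_denoise(v, g, p)$data
  flipped <- psnlm_denoise(flip1(v), flip1(g), p)$data
  expect_equal(flip1(straight), flipped, tolerance = 1e-13)
})

test_that("guiding with the volume itself reproduces classic NLM", {
  set.seed(408)
  v <- array(runif(7^3), c(7, 7, 7))
  p <- nlm_params(patch_size = 3, search_size = 5, h = 0.4)
  expect_identical(psnlm_denoise(v, v, p)$data, nlm_denoise(v, p)$data)
  # constant guidance collapses the weights to the windowed mean
  const_guide <- array(1, c(7, 7, 7))
  out <- psnlm_denoise(v, const_guide, p)$data
  box <- array(0, dim(v))
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    box[i, j, k] <- mean(v[max(1, i - 2):min(7, i + 2),
                           max(1, j - 2):min(7, j + 2),
                           max(1, k - 2):min(7, k + 2)])
  expect_equal(out, box, tolerance = 1e-12)
})

test_that("parameter validation catches bad NLM settings", {
  expect_error(nlm_params(patch_size = 4), "odd")
  expect_error(nlm_params(patch_size = 7, search_size = 5), "exceed")
  expect_error(nlm_params(h = -1), "positive")
  v <- array(1, c(4, 4, 4))
  expect_error(nlm_denoise(v, nlm_params(patch_size = 5, h = 1)),
               ">= patch_size")
  expect_error(psnlm_denoise(v, array(1, c(4, 4, 5)),
                             nlm_params(patch_size = 3, h = 1)),
               "mismatch")
})
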