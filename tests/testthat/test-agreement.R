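test_that("paired_readings validates shape and positive references", {
  expect_error(paired_readings(1:3, 1:2), "equal length")
  expect_error(paired_readings(1, 1), "at least 2")
  expect_error(paired_readings(c(1, 2), c(0, 2)), "> 0")
  p <- paired_readings(c(88, 90), c(88, 91), "heart_rate")
  expect_equal(p$K, 2)
})

test_that("error statistics agree with forced arithmetic", {
  p <- paired_readings(c(2, 3), c(1, 3))
  expect_equal(rmse(p), sqrt(0.5))
  expect_equal(mae(p), 0.5)
  expect_equal(mre(p), 0.5)  # (1/2)(|1-2|/1 + 0)
  ident <- paired_readings(c(5, 7, 9), c(5, 7, 9))
  expect_equal(rmse(ident), 0)
  expect_equal(mae(ident), 0)
  expect_equal(mre(ident), 0)
  expect_equal(mre(p, percent = TRUE), 100 * mre(p))
})

test_that("per-reading percentage error matches hand-checked cases", {
  expect_equal(per_reading_error(107, 104), 2.88)
  expect_equal(per_reading_error(88, 88), 0)
  expect_equal(per_reading_error(34.75, 34.6), 0.43)
  expect_error(per_reading_error(1, 0), "> 0")
})

test_that("a perfect-match device fits the identity line with r2 = 1", {
  p <- paired_readings(c(60, 80, 100, 120), c(60, 80, 100, 120))
  fit <- linear_fit(p)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_error(linear_fit(paired_readings(c(5, 5, 5), c(4, 5, 6))),
               "degenerate")
})

test_that("Bland-Altman uses measured-minus-reference and sample SD", {
  # differences {-1,+1,-1,+1}: mean 0, sample SD sqrt(4/3)
  p <- paired_readings(c(9, 11, 9, 11), c(10, 10, 10, 10))
  ba <- bland_altman(p)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3))
  expect_equal(ba$loa_upper, 1.96 * sqrt(4 / 3))
  expect_equal(ba$loa_lower, -1.96 * sqrt(4 / 3))
  expect_equal(ba$points$difference, c(-1, 1, -1, 1))
  expect_equal(ba$points$average, c(9.5, 10.5, 9.5, 10.5))
  expect_equal(ba$n_outside_loa, 0)
  # population divisor is available and recorded
  bp <- bland_altman(p, "population")
  expect_equal(bp$sd_diff, 1)
  expect_equal(bp$sd_divisor, "population")
  # degenerate: identical pairs give zero-width limits
  z <- bland_altman(paired_readings(c(3, 4, 5), c(3, 4, 5)))
  expect_equal(c(z$loa_lower, z$loa_upper), c(0, 0))
  expect_equal(z$n_outside_loa, 0)
})

test_that("statistics match the brute-force oracle on random tables", {
  withr::with_seed(42, {
    for (k in 1:50) {
      p <- random_pairs(sample(3:40, 1))
      o <- oracle_stats(p$pairs$measured, p$pairs$reference)
      fit <- linear_fit(p)
      ba <- bland_altman(p)
      expect_equal(rmse(p), o$rmse, tolerance = 1e-12)
      expect_equal(mae(p), o$mae, tolerance = 1e-12)
      expect_equal(mre(p), o$mre, tolerance = 1e-12)
      expect_equal(fit$slope, o$slope, tolerance = 1e-12)
      # intercept compared at 1e-12 relative to the reading scale (it is a
      # small difference of large terms)
      expect_lte(abs(fit$intercept - o$intercept),
                 1e-12 * mean(p$pairs$reference))
      expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-12)
      expect_lte(abs(ba$mean_diff - o$mean_diff),
                 1e-12 * mean(p$pairs$reference))
      expect_equal(ba$sd_diff, o$sd_diff, tolerance = 1e-12)
      expect_equal(ba$loa_upper, o$loa_upper, tolerance = 1e-12)
      expect_equal(ba$n_outside_loa, o$n_outside_loa)
    }
  })
})

test_that("rmse dominates mae, and both respect symmetry and scaling", {
  withr::with_seed(11, {
    for (k in 1:25) {
      p <- random_pairs(sample(3:30, 1))
      expect_gte(rmse(p), mae(p))
      # permutation invariance
      idx <- sample(p$K)
      ps <- paired_readings(p$pairs$measured[idx], p$pairs$reference[idx])
      expect_equal(rmse(ps), rmse(p))
      expect_equal(mae(ps), mae(p))
      expect_equal(linear_fit(ps)$r_squared, linear_fit(p)$r_squared)
      # unit equivariance under a common positive rescaling
      c0 <- runif(1, 0.1, 10)
      pc <- paired_readings(c0 * p$pairs$measured, c0 * p$pairs$reference)
      expect_equal(rmse(pc), c0 * rmse(p))
      expect_equal(mae(pc), c0 * mae(p))
      expect_equal(mre(pc), mre(p))
      expect_equal(linear_fit(pc)$r_squared, linear_fit(p)$r_squared)
      bao <- bland_altman(p); bac <- bland_altman(pc)
      expect_equal(bac$mean_diff, c0 * bao$mean_diff)
      expect_equal(bac$loa_upper, c0 * bao$loa_upper)
    }
    # equality of rmse and mae iff all absolute differences equal
    pe <- paired_readings(c(11, 9, 11), c(10, 10, 10))
    expect_equal(rmse(pe), mae(pe))
  })
})

test_that("about 95 percent of Gaussian differences fall inside the limits", {
  withr::with_seed(2024, {
    ref <- runif(10000, 50, 150)
    mes <- ref + rnorm(10000)
    ba <- bland_altman(paired_readings(mes, ref))
    frac_inside <- 1 - ba$n_outside_loa / 10000
    expect_true(abs(frac_inside - 0.95) <= 0.02)
  })
})

test_that("the composed report carries consistent internal structure", {
  p <- load_fixture("hr")
  rep <- agreement_report(p)
  expect_gte(rep$rmse, rep$mae)
  expect_gte(rep$loa_upper, rep$mean_diff)
  expect_lte(rep$loa_lower, rep$mean_diff)
  expect_true(rep$r_squared >= 0 && rep$r_squared <= 1)
  expect_equal(rep$mre_percent, 100 * rep$mre)
  df <- as.data.frame(rep)
  expect_equal(df$rmse, rep$rmse)
  expect_output(print(rep), "Bland-Altman")
})
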