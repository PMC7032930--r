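test_that("surrogate specs validate their ranges", {
  expect_error(surrogate_spec(100, active_fraction = 0), "active_fraction")
  expect_error(surrogate_spec(100, target_r = 1.2), "target_r")
})

test_that("extreme targets give identical or independent vectors", {
  v1 <- correlated_rate_vectors(surrogate_spec(500, 20, target_r = 1,
                                               seed = 3))
  expect_identical(v1$a, v1$b)
  v0 <- correlated_rate_vectors(surrogate_spec(4000, 20, target_r = 0,
                                               seed = 4))
  expect_lt(abs(cor(v0$a, v0$b)), 0.05)
})

test_that("sample Pearson R is unbiased at the programmed target", {
  rs <- vapply(1:100, function(s)
    with(correlated_rate_vectors(surrogate_spec(2000, 10, target_r = 0.5,
                                                seed = s)),
         cor(a, b)),
    numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.02)
  # sparsity matches in expectation
  v <- correlated_rate_vectors(surrogate_spec(20000, 10, 0.3, seed = 9))
  expect_equal(mean(v$a > 0) * 100, 10, tolerance = 1)
})

test_that("rasters recover their generating rates", {
  expect_equal(nrow(raster_from_rates(rep(0, 50), 600, 1)$spikes), 0)
  # 5 Hz cell for 600 ms: mean 3 spikes
  n <- vapply(1:300, function(s)
    nrow(raster_from_rates(5, 600, seed = s)$spikes), numeric(1))
  expect_equal(mean(n), 3, tolerance = 0.1)
  # round-trip at n = 2000
  rates <- correlated_rate_vectors(surrogate_spec(2000, 10, 0.5, seed = 2))$a
  ras <- raster_from_rates(rates, 5000, seed = 5)
  back <- rate_vector(ras, "gc", c(0, 5000))
  expect_gt(cor(back, rates), 0.9)
  expect_equal(mean(back), mean(rates), tolerance = 0.1)
})

test_that("a programmed R_in to R_out mapping is recovered end to end", {
  # pairs with known input and output correlations: R_out = R_in - 0.1
  set.seed(10)
  n_pairs <- 400
  r_in_t <- runif(n_pairs, 0.15, 0.95)
  pairs <- data.frame(p = seq_len(n_pairs), q = seq_len(n_pairs),
                      r_in = NA_real_, r_out = NA_real_)
  for (k in seq_len(n_pairs)) {
    vin <- correlated_rate_vectors(surrogate_spec(2000, 15, r_in_t[k],
                                                  seed = k))
    vout <- correlated_rate_vectors(surrogate_spec(2000, 8,
                                                   max(r_in_t[k] - 0.1, 0),
                                                   seed = k + 5000))
    pairs$r_in[k] <- cor(vin$a, vin$b)
    pairs$r_out[k] <- cor(vout$a, vout$b)
  }
  curve <- binwise_curve(pairs)
  got <- mean_delta_rout_full(curve)
  expect_lt(abs(got - 0.1), 0.01)
})
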