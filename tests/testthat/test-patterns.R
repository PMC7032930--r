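test_that("rate profile starts at the trough and oscillates over [min, peak]", {
  f <- rate_profile(10, 100, 0)
  expect_equal(f(0), 0)
  expect_equal(f(50), 100)           # half a theta cycle later
  expect_equal(f(100), 0)            # full cycle
  tt <- seq(0, 600, by = 0.1)
  expect_gte(min(f(tt)), 0)
  expect_lte(max(f(tt)), 100)
  # 6 full cycles in 600 ms: peaks at 50, 150, ..., 550 ms
  peaks <- tt[f(tt) > 99.99]
  expect_equal(length(unique(floor(peaks / 100))), 6)
  # time average of the sinusoid = (peak + min) / 2
  expect_equal(mean(f(tt)), 50, tolerance = 1e-3)
})

test_that("degenerate and invalid profiles are handled", {
  expect_error(rate_profile(10, 50, 80), "peak")
  const <- rate_profile(10, 40, 40)
  expect_equal(const(c(0, 13, 200)), rep(40, 3))
})

test_that("inhomogeneous Poisson matches its analytic expectations", {
  # zero rate: empty train
  expect_length(inhomogeneous_poisson(0, 600, seed = 1), 0)
  # theta profile: mean count = 50 Hz * 0.6 s = 30
  prof <- rate_profile(10, 100, 0)
  counts <- vapply(1:400, function(s)
    length(inhomogeneous_poisson(prof, 600, seed = s)), numeric(1))
  expect_equal(mean(counts), 30, tolerance = 0.05)
  # determinism per seed
  expect_identical(inhomogeneous_poisson(prof, 600, seed = 7),
                   inhomogeneous_poisson(prof, 600, seed = 7))
  expect_error(inhomogeneous_poisson(function(t) -1 + 0 * t, 100, 1),
               "negative")
})

test_that("constant-rate counts are Poisson distributed (chi-square)", {
  counts <- vapply(1:600, function(s)
    length(inhomogeneous_poisson(100, 600, seed = 1000 + s)), numeric(1))
  # bin the distribution against Poisson(60)
  brk <- c(-Inf, 49, 55, 60, 65, 71, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(c(-Inf, 49, 55, 60, 65, 71, Inf), 60))
  p <- suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value)
  expect_gt(p, 0.01)
})

test_that("pattern families implement the sliding-window overlap rule", {
  cfg <- input_config(seed_input = 5)
  fam <- generate_pattern_family(cfg)
  expect_length(fam$afferents, 25)
  expect_equal(fam$afferents[[1]], 1:24)
  expect_equal(fam$afferents[[25]], 25:48)
  # overlap rule: max(0, 24 - |p - q|)
  for (pair in list(c(1, 1), c(1, 13), c(1, 25), c(3, 10))) {
    ov <- length(intersect(fam$afferents[[pair[1]]],
                           fam$afferents[[pair[2]]]))
    expect_equal(ov, max(0, 24 - abs(diff(pair))))
  }
  # shared afferents carry bit-identical trains in every pattern
  d1 <- pattern_drive(fam, 1)
  d2 <- pattern_drive(fam, 2)
  for (a in intersect(fam$afferents[[1]], fam$afferents[[2]]))
    expect_identical(d1[[a]], d2[[a]])
})

test_that("family overflow beyond the afferent range is rejected", {
  expect_error(input_config(n_afferents = 40, pattern_size = 24,
                            n_patterns = 25, increment = 1),
               "overflow")
})

test_that("mean input rate is independent of the modulation frequency", {
  c10 <- input_config(mod_freq = 10, seed_input = 1)
  c30 <- input_config(mod_freq = 30, seed_input = 1)
  n10 <- sum(lengths(generate_pattern_family(c10)$trains))
  n30 <- sum(lengths(generate_pattern_family(c30)$trains))
  # 48 afferents x 30 expected spikes each
  expect_equal(n10 / 48, 30, tolerance = 0.12)
  expect_equal(n30 / 48, 30, tolerance = 0.12)
  expect_equal(n10, n30, tolerance = 0.1)
})

test_that("input R_in decreases with pattern distance on average", {
  fam <- small_family()
  m <- family_rate_matrix(fam)
  r_by_d <- vapply(c(1, 6, 12, 18, 24), function(d) {
    mean(vapply(seq_len(25 - d), function(p)
      cor(m[, p], m[, p + d]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r_by_d) < 0))
  expect_lt(abs(r_by_d[5]), 0.1)   # disjoint patterns near zero
})
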