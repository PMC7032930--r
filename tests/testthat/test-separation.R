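raster <- function(times_by_cell, n = length(times_by_cell),
                   duration = 600) {
  cells <- rep(seq_along(times_by_cell), lengths(times_by_cell))
  structure(list(
    spikes = data.frame(population = rep("gc", length(cells)),
                        cell = cells, time = unlist(times_by_cell)),
    counts = c(pp = 0L, gc = n, bc = 0L, hc = 0L, mc = 0L),
    condition = "TEST", duration = duration, dt = 0.1,
    seed_network = 1L),
    class = "dg_sim_result")
}

test_that("rate vectors are counts over the window length", {
  r <- raster(list(c(10, 110, 500), numeric(0), 599.9), n = 4)
  rv <- rate_vector(r, "gc")
  expect_equal(rv, c(3, 0, 1, 0) / 0.6)
  # windowed rates average back to the full-window rate
  wins <- lapply(0:5, function(k) rate_vector(r, "gc", c(k * 100, (k + 1) * 100)))
  expect_equal(Reduce(`+`, wins) / 6, rv)
  expect_error(rate_vector(r, "gc", c(100, 100)), "empty")
  expect_error(rate_vector(r, "gc", c(0, 700)), "beyond")
})

test_that("similarity measures agree with hand oracles", {
  a <- c(1, 2, 0, 0); b <- c(0, 2, 1, 0)
  expect_equal(similarity(a, b, "overlap"), 1 / 3)
  expect_equal(similarity(a, b, "ndp"), 4 / 5)
  expect_equal(similarity(a, b, "pearson"), 7 / 11)
  expect_equal(similarity(a, b, "pearson"), oracle_pearson(a, b))
  # identity and disjoint support
  expect_equal(similarity(a, a, "pearson"), 1)
  expect_equal(similarity(a, a, "ndp"), 1)
  expect_equal(similarity(a, a, "overlap"), 1)
  d <- c(0, 0, 3, 1)
  expect_equal(similarity(a, d, "overlap"), 0)
  expect_equal(similarity(a, d, "ndp"), 0)
  # random vectors: all three match the oracles, symmetrically
  set.seed(42)
  for (i in 1:20) {
    x <- rpois(30, 2) * runif(30); y <- rpois(30, 2) * runif(30)
    for (m in c("pearson", "ndp", "overlap")) {
      ora <- switch(m, pearson = oracle_pearson, ndp = oracle_ndp,
                    overlap = oracle_overlap)
      expect_equal(similarity(x, y, m), ora(x, y), tolerance = 1e-12)
      expect_equal(similarity(x, y, m), similarity(y, x, m))
    }
  }
})

test_that("undefined similarities are flagged as missing", {
  z <- rep(0, 5); c5 <- rep(2, 5)
  expect_true(is.na(similarity(z, 1:5, "pearson")))
  expect_true(is.na(similarity(c5, 1:5, "pearson")))  # zero variance
  expect_true(is.na(similarity(z, 1:5, "ndp")))
  expect_true(is.na(similarity(z, z, "overlap")))
})

test_that("pair counts follow the with/without-self identities", {
  fam <- small_family()
  m_out <- matrix(runif(50 * 25), 50, 25)
  fake <- lapply(1:25, function(p) {
    counts <- round(m_out[, p] * 3)
    raster(lapply(counts, function(k) sort(runif(k, 0, 600))), n = 50)
  })
  with_self <- all_pairs(fake, fam, "pearson", with_self = TRUE)
  without <- all_pairs(fake, fam, "pearson", with_self = FALSE)
  expect_equal(nrow(with_self), 325)
  expect_equal(nrow(without), 300)
  expect_equal(with_self$r_in[with_self$p == with_self$q],
               rep(1, 25))
  # n = 2 gives a single unordered pair
  fam2 <- fam; fam2$cfg$n_patterns <- 2L
  fam2$afferents <- fam2$afferents[1:2]
  expect_equal(nrow(all_pairs(fake[1:2], fam2, with_self = FALSE)), 1)
  # mixed conditions are rejected
  bad <- fake; bad[[3]]$condition <- "OTHER"
  expect_error(all_pairs(bad, fam), "conditions")
})

test_that("binwise curve matches a brute-force group-by", {
  set.seed(7)
  pairs <- data.frame(r_in = runif(400), r_out = runif(400))
  curve <- binwise_curve(pairs)
  ora <- oracle_binwise(pairs$r_in, pairs$r_out)
  expect_equal(curve$mean_r_in, ora$mean_r_in)
  expect_equal(curve$mean_response, ora$mean_y)
  # r_in = 1 joins the top bin; single pair occupies one bin
  one <- binwise_curve(data.frame(r_in = 1, r_out = 0.5))
  expect_equal(sum(one$n), 1)
  expect_equal(one$n[10], 1L)
})

test_that("mean separation behaves as arithmetic dictates", {
  # identity mapping: zero separation
  pairs <- data.frame(r_in = seq(0.05, 0.95, by = 0.1),
                      r_out = seq(0.05, 0.95, by = 0.1))
  expect_equal(mean_delta_rout_full(binwise_curve(pairs)), 0)
  # r_out = 0 with bin means at 0.05 ... 0.95: area 0.5
  pairs$r_out <- 0
  expect_equal(mean_delta_rout_full(binwise_curve(pairs)), 0.5)
  # r_out = r_in / 2: mean of binwise r_in / 2
  pairs$r_out <- pairs$r_in / 2
  expect_equal(mean_delta_rout_full(binwise_curve(pairs)),
               mean(pairs$r_in) / 2)
})

test_that("isolated effects subtract pairwise and commute with averaging", {
  set.seed(8)
  a <- data.frame(p = rep(1:10, each = 10), q = rep(1:10, 10),
                  r_in = runif(100), r_out = runif(100))
  b <- a
  b$r_out <- a$r_out + 0.1
  d <- isolated_effect(a, b)
  expect_equal(d$delta, rep(0.1, 100))
  expect_equal(mean_delta_isolated(d), 0.1, tolerance = 1e-12)
  # A = B: identically zero
  expect_true(all(isolated_effect(a, a)$delta == 0))
  # subtract-then-average equals average-then-subtract, binwise
  b$r_out <- runif(100)
  d <- isolated_effect(a, b)
  ca <- binwise_curve(a); cb <- binwise_curve(b)
  cd <- binwise_curve(d, "delta")
  occ <- !is.na(cd$mean_response)
  expect_equal(cd$mean_response[occ],
               (cb$mean_response - ca$mean_response)[occ])
  # shuffled row order still matches by key; missing keys are an error
  d2 <- isolated_effect(a, b[sample(100), ])
  expect_equal(d2$delta, d$delta)
  expect_error(isolated_effect(a, b[-5, ]), "unmatched|match")
})

test_that("the band mean summarises highly similar pairs", {
  pairs <- data.frame(p = 1:4, q = 1:4, r_in = c(0.95, 0.92, 0.5, 1),
                      delta = c(0.1, 0.2, 9, 0.3))
  expect_equal(band_mean(pairs, "delta"), 0.2)
  expect_true(is.na(band_mean(pairs[pairs$r_in < 0.5, ], "delta")))
})

test_that("CoV uses sample SD over mean within 0.2 < R_in < 0.8", {
  # one occupied bin with values {1, 3}: sd sqrt(2), mean 2
  pd <- data.frame(p = 1:2, q = 1:2, r_in = c(0.55, 0.57), delta = c(1, 3))
  class(pd) <- c("dg_pairs_delta", "data.frame")
  expect_equal(cov_delta(pd), sqrt(2) / 2)
  # constant delta in every bin: CoV 0
  pd2 <- data.frame(r_in = runif(50, 0.25, 0.75), delta = 0.2)
  expect_equal(cov_delta(pd2), 0)
  # bins outside (0.2, 0.8) are ignored regardless of content
  pd3 <- rbind(pd2, data.frame(r_in = c(0.05, 0.95), delta = c(100, -100)))
  expect_equal(cov_delta(pd3), 0)
  expect_error(cov_delta(data.frame(r_in = c(0.05), delta = 1)), "0.2")
})

test_that("time-resolved analysis tiles the full window", {
  fam <- small_family()
  set.seed(9)
  fake <- lapply(1:25, function(p)
    raster(lapply(1:50, function(i) sort(runif(rpois(1, 2), 0, 600))),
           n = 50))
  tr <- time_resolved(fake, fam, window_len = 100)
  expect_length(tr, 6)
  expect_equal(tr[[3]]$window, c(200, 300))
  # windowed spike counts sum to the full-window counts
  full <- rate_vector(fake[[1]], "gc") * 0.6
  summed <- Reduce(`+`, lapply(tr, function(w)
    rate_vector(fake[[1]], "gc", w$window) * 0.1))
  expect_equal(summed, full)
  expect_warning(time_resolved(fake, fam, window_len = 250), "partial")
  expect_error(time_resolved(fake, fam, window_len = 700), "exceeds")
})

test_that("activity metrics count active cells exactly", {
  r <- raster(list(c(10, 20), numeric(0), 30, numeric(0)), n = 4)
  m <- activity_metrics(r)
  expect_equal(m$active_fraction, 50)
  expect_equal(m$mean_rate_active, mean(c(2, 1) / 0.6))
  r0 <- raster(list(numeric(0)), n = 3)
  expect_equal(activity_metrics(r0)$active_fraction, 0)
})
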