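test_that("the model has no spontaneous activity", {
  net <- small_net()
  res <- run_simulation(net, duration = 200)
  expect_equal(nrow(res$spikes), 0)
})

test_that("simulations are bit-reproducible and truncation warns", {
  net <- small_net()
  fam <- small_family()
  drv <- pattern_drive(fam, 1)
  r1 <- run_simulation(net, drive = drv, duration = 300)
  r2 <- run_simulation(net, drive = drv, duration = 300)
  expect_identical(r1$spikes, r2$spikes)
  expect_gt(nrow(r1$spikes), 0)
  expect_warning(run_simulation(net, drive = drv, duration = 100),
                 "truncated")
  expect_error(run_simulation(net, drive = drv, dt = 0.5), "dt")
  too_many <- c(drv, list(c(1, 2)))
  expect_error(run_simulation(net, drive = too_many), "afferent")
})

test_that("disinhibition increases the active GC fraction", {
  net <- small_net()
  fam <- small_family()
  drv <- pattern_drive(fam, 5)
  full <- run_simulation(net, drive = drv)
  nofb <- run_simulation(apply_condition(net, "NO_FB"), drive = drv)
  noin <- run_simulation(apply_condition(net, "NO_INHIBITION"), drive = drv)
  af <- vapply(list(full, nofb, noin), function(r)
    activity_metrics(r)$active_fraction, numeric(1))
  expect_lt(af[1], af[2])
  expect_lte(af[2], af[3])
})

test_that("a single driven GC excites the hilus but evokes no feedback IPSC", {
  net <- small_net()
  probe <- 250L
  # drive one GC far from the probe hard (10 spikes at 100 Hz)
  inj <- data.frame(cell = 100L, start = seq(20, 110, by = 10),
                    duration = 2, amplitude = 5000)
  res <- run_simulation(net, injections = inj, probes = probe,
                        duration = 250)
  gc_spk <- res$spikes[res$spikes$population == "gc", ]
  expect_gte(nrow(gc_spk), 8)
  expect_true(all(gc_spk$cell == 100))
  # no interneuron fires, hence no IPSC at the probe
  expect_equal(sum(res$spikes$population %in% c("bc", "hc")), 0)
  expect_lt(max(res$probe_ipsc), 1e-9)
})

test_that("spike tables round-trip through the TSV format", {
  net <- small_net()
  fam <- small_family()
  res <- run_simulation(net, drive = pattern_drive(fam, 2), duration = 300)
  path <- tempfile(fileext = ".tsv")
  write_spikes(res, path)
  back <- read_spikes(path)
  expect_equal(back$spikes, res$spikes)
  expect_equal(back$counts, res$counts)
  expect_equal(back$condition, res$condition)
  # file is 0-based on disk
  raw <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(min(raw$cell_id), min(res$spikes$cell) - 1L)
})
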