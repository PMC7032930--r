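test_that("the default configuration reproduces the lamella census", {
  cfg <- network_config()
  expect_equal(unname(cfg$counts), c(400L, 2000L, 24L, 24L, 60L))
  expect_equal(cfg$lamella_length, 2000)
  # proportional down-scaling with rounding
  cfg4 <- network_config(scale = 0.25)
  expect_equal(unname(cfg4$counts), c(100L, 500L, 6L, 6L, 15L))
  # desk preset keeps the input space
  cfg4k <- network_config(scale = 0.25, keep_input = TRUE)
  expect_equal(unname(cfg4k$counts), c(400L, 500L, 6L, 6L, 15L))
})

test_that("building is deterministic and positions span the lamella", {
  cfg <- network_config(scale = 0.25)
  n1 <- build_network(cfg, seed = 3)
  n2 <- build_network(cfg, seed = 3)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$cell_vth, n2$cell_vth)
  n3 <- build_network(cfg, seed = 4)
  expect_false(identical(n1$edges, n3$edges))
  for (p in c("gc", "bc", "hc", "mc")) {
    expect_true(all(n1$positions[[p]] >= 0 &
                      n1$positions[[p]] <= cfg$lamella_length))
  }
  # no MC -> GC edges by construction
  expect_false("mc_gc" %in% n1$edges$class)
  # PP feeds both GC (input) and BC (feedforward)
  expect_true(all(c("pp_gc", "pp_bc") %in% n1$edges$class))
})

test_that("wiring respects divergence and spatial pools", {
  net <- small_net()
  cfg <- net$config
  # every PP contacts the scaled number of distinct GCs
  ppgc <- net$edges[net$edges$class == "pp_gc", ]
  deg <- table(ppgc$pre_unit)
  expect_true(all(deg == 25))  # 100 * (500 / 2000)
  expect_equal(anyDuplicated(paste(ppgc$pre_unit, ppgc$post_cell)), 0)
  # BC outputs stay within the ~600 um pool
  bcgc <- net$edges[net$edges$class == "bc_gc", ]
  bc_pos <- net$positions$bc[bcgc$pre_unit - net$counts[["pp"]] -
                               net$offsets[["bc"]] + 1]
  gc_pos <- net$positions$gc[bcgc$post_cell + 1]
  expect_true(all(abs(bc_pos - gc_pos) <= 300 + 1e-9))
})

test_that("divergence larger than the target pool is a config error", {
  ct <- default_connectivity_table()
  ct$bc_gc <- connectivity_rule(10000, 600, "uniform")
  cfg <- network_config(connectivity_table = ct)
  expect_error(build_network(cfg, seed = 1), "bc_gc")
})

test_that("conditions change only their declared parameters", {
  net <- small_net()
  mf <- c("gc_bc", "gc_hc", "gc_mc")

  full <- apply_condition(net, "FULL")
  expect_identical(full$edges, net$edges)

  nofb <- apply_condition(net, "NO_FB")
  expect_true(all(nofb$edges$weight[nofb$edges$class %in% mf] == 0))
  aud <- audit_conditions(net, nofb)
  expect_setequal(aud$class[aud$weights_differ], mf)
  expect_false(any(aud$wiring_differs))
  expect_false(any(aud$params_differ))

  noin <- apply_condition(net, "NO_INHIBITION")
  aud <- audit_conditions(net, noin)
  expect_setequal(aud$class[aud$weights_differ], c("bc_gc", "hc_gc"))

  ffx2 <- apply_condition(net, "FF_X2")
  expect_equal(ffx2$edges$weight[ffx2$edges$class == "pp_bc"],
               2 * net$edges$weight[net$edges$class == "pp_bc"])
  aud <- audit_conditions(net, ffx2)
  expect_setequal(aud$class[aud$weights_differ], "pp_bc")

  nofac <- apply_condition(net, "NO_FACILITATION")
  expect_true(all(nofac$class_table$tau_facil[
    nofac$class_table$name %in% mf] == 0))
  expect_identical(nofac$edges, net$edges)

  tau2 <- apply_condition(net, "TAU_SCALE", factor = 2)
  inh <- net$class_table$e_rev < -50
  expect_equal(tau2$class_table$tau_decay[inh],
               2 * net$class_table$tau_decay[inh])
  expect_identical(tau2$class_table$tau_decay[!inh],
                   net$class_table$tau_decay[!inh])
  expect_error(apply_condition(net, "TAU_SCALE", factor = 10))

  pp05 <- apply_condition(net, "PP_SCALE", factor = 0.5)
  expect_equal(pp05$edges$weight[pp05$edges$class == "pp_gc"],
               0.5 * net$edges$weight[net$edges$class == "pp_gc"])

  expect_error(apply_condition(net, "WHATEVER"), "unknown")
  expect_error(apply_condition(nofb, "NO_INHIBITION"), "FULL")
})

test_that("GLOBAL_FB keeps BC out-degree but spans the whole lamella", {
  net <- small_net()
  glob <- apply_condition(net, "GLOBAL_FB")
  for (nt in list(net, glob)) nt$edges$class <- as.character(nt$edges$class)
  deg0 <- table(net$edges$pre_unit[net$edges$class == "bc_gc"])
  deg1 <- table(glob$edges$pre_unit[glob$edges$class == "bc_gc"])
  expect_equal(deg0, deg1)
  bcgc <- glob$edges[glob$edges$class == "bc_gc", ]
  bc_pos <- glob$positions$bc[bcgc$pre_unit - glob$counts[["pp"]] -
                                glob$offsets[["bc"]] + 1]
  gc_pos <- glob$positions$gc[bcgc$post_cell + 1]
  expect_gt(max(abs(bc_pos - gc_pos)), 500)  # targets far outside the pool
  aud <- audit_conditions(net, glob)
  expect_setequal(aud$class[aud$wiring_differs], "bc_gc")
})

test_that("configurations survive a JSON round trip", {
  cfg <- network_config(scale = 0.5, dt = 0.1, seed_network = 9L)
  path <- tempfile(fileext = ".json")
  write_network_config(cfg, path)
  back <- read_network_config(path)
  expect_equal(back$counts, cfg$counts)
  expect_equal(back$synapse_table, cfg$synapse_table)
  expect_equal(back$connectivity_table, cfg$connectivity_table)
  expect_equal(unname(back$cell_params), unname(cfg$cell_params),
               tolerance = 1e-12)
  # identical wiring from the restored configuration
  expect_identical(build_network(cfg, 2)$edges,
                   build_network(back, 2)$edges)
})

test_that("PP wiring approaches uniformity as the gaussian SD grows", {
  ct <- default_connectivity_table()
  ct$pp_gc <- connectivity_rule(100, "global", "gaussian", sd = 1e7)
  cfg <- network_config(connectivity_table = ct)
  net <- build_network(cfg, seed = 6)
  tgt <- net$edges$post_cell[net$edges$class == "pp_gc"]
  pos <- net$positions$gc[tgt + 1]
  ks <- suppressWarnings(ks.test(pos, "punif", 0, 2000))
  expect_gt(ks$p.value, 0.01)
})
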