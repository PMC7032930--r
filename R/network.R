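#' Build the lamella network
#'
#' Instantiates all edge classes of the configuration. Cells of every
#' population are spread evenly over the lamella; each presynaptic cell
#' makes `divergence` synapses onto distinct targets drawn from its spatial
#' target pool (clipped at the lamella boundaries). Mossy-cell to
#' granule-cell connections are absent by construction (extralamellar).
#' Perforant-path wiring (PP->GC gaussian divergence and PP->BC feedforward
#' edges) is drawn by [connect_pp()], which this function calls with a seed
#' derived from `seed`.
#'
#' Wiring is fully reproducible: the same `(config, seed)` produce
#' identical edge lists.
#'
#' @param config a [network_config()]
#' @param seed wiring seed (defaults to `config$seed_network`)
#' @return an object of class `dg_network`
#' @export
build_network <- function(config, seed = config$seed_network) {
  stopifnot(inherits(config, "dg_network_config"))
  counts <- config$counts
  L <- config$lamella_length
  pops <- c("gc", "bc", "hc", "mc")
  positions <- lapply(c(pp = "pp", setNames(pops, pops)), function(p) {
    n <- counts[[p]]
    (seq_len(n) - 0.5) * L / n
  })
  offsets <- c(gc = 0L, bc = counts[["gc"]],
               hc = counts[["gc"]] + counts[["bc"]],
               mc = counts[["gc"]] + counts[["bc"]] + counts[["hc"]])
  n_cells <- sum(counts[pops])
  cell_type <- rep(0:3, times = counts[pops])

  net <- structure(list(
    config = config, counts = counts, offsets = offsets,
    positions = positions, cell_type = cell_type,
    cell_vth = numeric(n_cells), pp_peaks = NULL,
    edges = NULL, class_table = NULL,
    condition = "FULL", seed_network = as.integer(seed),
    cache = new.env(parent = emptyenv())),
    class = "dg_network")

  cls_names <- names(config$synapse_table)
  net$class_table <- data.frame(
    name = cls_names,
    tau_decay = vapply(config$synapse_table, `[[`, 0, "tau_decay"),
    tau_facil = vapply(config$synapse_table, `[[`, 0, "tau_facil"),
    U = vapply(config$synapse_table, `[[`, 0, "U"),
    delay = vapply(config$synapse_table, `[[`, 0, "delay"),
    e_rev = vapply(config$synapse_table, `[[`, 0, "e_rev"),
    row.names = NULL)

  with_seed(derive_seed(seed, "network"), {
    # per-cell threshold heterogeneity
    vth <- numeric(n_cells)
    for (p in pops) {
      ty <- match(p, pops) - 1L
      idx <- which(cell_type == ty)
      base <- config$cell_params[p, "Vth"]
      j <- config$vth_jitter[[p]]
      vth[idx] <- base + runif(length(idx), -j, j)
    }
    net$cell_vth <- vth

    # all non-PP edge classes
    edge_list <- list()
    for (cn in setdiff(cls_names, c("pp_gc", "pp_bc"))) {
      edge_list[[cn]] <- draw_edges(net, cn)
    }
    net$edges <- do.call(rbind, edge_list)
  })
  net <- connect_pp(net, seed = derive_seed(seed, "pp"))
  rownames(net$edges) <- NULL
  net
}

# Draw the edge table for one class from the connectivity rule, preserving
# the scale-1 convergent weight sum: divergence shrinks with the target
# population and the weight is multiplied by the ratio of reference to
# realised convergence.
draw_edges <- function(net, class_name, pool_override = NULL) {
  cfg <- net$config
  rule <- cfg$connectivity_table[[class_name]]
  spec <- cfg$synapse_table[[class_name]]
  ends <- edge_populations(class_name)
  n_pre <- net$counts[[ends$pre]]
  n_post <- net$counts[[ends$post]]
  n_pre_b <- cfg$base_counts[[ends$pre]]
  n_post_b <- cfg$base_counts[[ends$post]]

  div <- max(1L, as.integer(round(rule$divergence * n_post / n_post_b)))
  conv_base <- n_pre_b * rule$divergence / n_post_b
  conv_eff <- n_pre * div / n_post
  w <- spec$weight * conv_base / conv_eff

  pool_extent <- if (is.null(pool_override)) rule$pool_extent else pool_override
  pre_pos <- net$positions[[ends$pre]]
  post_pos <- net$positions[[ends$post]]
  post_offset <- if (ends$post == "pp") stop("PP cannot be postsynaptic")
                 else net$offsets[[ends$post]]

  pre_unit0 <- if (ends$pre == "pp") 0L else net$counts[["pp"]] +
    net$offsets[[ends$pre]]

  out <- vector("list", n_pre)
  for (i in seq_len(n_pre)) {
    if (identical(pool_extent, "global")) {
      pool <- seq_len(n_post)
    } else {
      half <- pool_extent / 2
      pool <- which(abs(post_pos - pre_pos[i]) <= half)
    }
    # a cell never synapses onto itself
    if (ends$pre == ends$post) pool <- setdiff(pool, i)
    if (div > length(pool)) {
      if (div > n_post)
        stop(sprintf("edge class '%s': divergence %d exceeds target pool size %d",
                     class_name, div, length(pool)))
      # sparse down-scaled populations: widen the pool to the nearest
      # targets so every cell keeps its out-degree
      ranked <- order(abs(post_pos - pre_pos[i]))
      if (ends$pre == ends$post) ranked <- setdiff(ranked, i)
      pool <- ranked[seq_len(div)]
    }
    if (rule$profile == "gaussian") {
      pk <- dnorm(post_pos[pool], mean = pre_pos[i], sd = rule$sd)
      tgt <- pool[sample.int(length(pool), div, prob = pk)]
    } else {
      tgt <- pool[sample.int(length(pool), div)]
    }
    out[[i]] <- data.frame(class = class_name,
                           pre_unit = pre_unit0 + i - 1L,
                           post_cell = post_offset + tgt - 1L,
                           weight = w)
  }
  do.call(rbind, out)
}

#' Wire the perforant path
#'
#' Draws PP->GC and PP->BC edges. Each PP afferent contacts a fixed number
#' of distinct granule cells sampled without replacement under a clipped
#' Gaussian spatial weighting (SD from the connectivity rule, default 1 mm)
#' centred on a random peak position on the lamella; feedforward PP->BC
#' edges follow the configured pool rule around the same peak. Existing PP
#' edges are replaced, everything else is untouched.
#'
#' @param network a `dg_network`
#' @param seed wiring seed for the PP stream
#' @return the network with PP edges attached
#' @export
connect_pp <- function(network, seed = derive_seed(network$seed_network, "pp")) {
  cfg <- network$config
  n_pp <- network$counts[["pp"]]
  n_gc <- network$counts[["gc"]]
  rule_gc <- cfg$connectivity_table[["pp_gc"]]
  rule_bc <- cfg$connectivity_table[["pp_bc"]]
  spec_gc <- cfg$synapse_table[["pp_gc"]]
  spec_bc <- cfg$synapse_table[["pp_bc"]]

  div_gc <- max(1L, as.integer(round(rule_gc$divergence * n_gc /
                                       cfg$base_counts[["gc"]])))
  if (div_gc > n_gc) stop("pp_gc: divergence exceeds GC population")
  conv_base <- cfg$base_counts[["pp"]] * rule_gc$divergence /
    cfg$base_counts[["gc"]]
  conv_eff <- n_pp * div_gc / n_gc
  w_gc <- spec_gc$weight * conv_base / conv_eff

  n_bc <- network$counts[["bc"]]
  div_bc <- max(1L, as.integer(round(rule_bc$divergence * n_bc /
                                       cfg$base_counts[["bc"]])))
  conv_base_bc <- cfg$base_counts[["pp"]] * rule_bc$divergence /
    cfg$base_counts[["bc"]]
  conv_eff_bc <- n_pp * div_bc / n_bc
  w_bc <- spec_bc$weight * conv_base_bc / conv_eff_bc

  gc_pos <- network$positions$gc
  bc_pos <- network$positions$bc
  L <- cfg$lamella_length

  with_seed(seed, {
    peaks <- runif(n_pp, 0, L)
    eg <- vector("list", n_pp)
    eb <- vector("list", n_pp)
    for (i in seq_len(n_pp)) {
      pk <- dnorm(gc_pos, mean = peaks[i], sd = rule_gc$sd)
      tgt <- sample.int(n_gc, div_gc, prob = pk)
      eg[[i]] <- data.frame(class = "pp_gc", pre_unit = i - 1L,
                            post_cell = network$offsets[["gc"]] + tgt - 1L,
                            weight = w_gc)
      half <- if (identical(rule_bc$pool_extent, "global")) Inf
              else rule_bc$pool_extent / 2
      pool <- which(abs(bc_pos - peaks[i]) <= half)
      if (length(pool) < div_bc) pool <- order(abs(bc_pos - peaks[i]))[seq_len(div_bc)]
      tb <- pool[sample.int(length(pool), div_bc)]
      eb[[i]] <- data.frame(class = "pp_bc", pre_unit = i - 1L,
                            post_cell = network$offsets[["bc"]] + tb - 1L,
                            weight = w_bc)
    }
    network$pp_peaks <- peaks
    keep <- !(network$edges$class %in% c("pp_gc", "pp_bc"))
    network$edges <- rbind(
      if (!is.null(network$edges)) network$edges[keep, ] else NULL,
      do.call(rbind, eg), do.call(rbind, eb))
  })
  rownames(network$edges) <- NULL
  network$cache <- new.env(parent = emptyenv())
  network
}

#' @export
print.dg_network <- function(x, ...) {
  cat(sprintf("dentate lamella network [%s]\n", x$condition))
  cat(sprintf("  PP %d | GC %d | BC %d | HC %d | MC %d on %g um\n",
              x$counts["pp"], x$counts["gc"], x$counts["bc"], x$counts["hc"],
              x$counts["mc"], x$config$lamella_length))
  tab <- table(x$edges$class)
  cat(sprintf("  %d edges in %d classes (seed %d)\n",
              nrow(x$edges), length(tab), x$seed_network))
  invisible(x)
}

#' Apply an experimental condition to a tuned network
#'
#' Returns a copy of the network in which only the parameters targeted by
#' the condition differ from the full tuned state:
#' \describe{
#'   \item{FULL}{identity.}
#'   \item{NO_FB}{mossy-fiber outputs to the feedback circuit
#'     (GC->BC, GC->HC, GC->MC) weights set to zero.}
#'   \item{NO_INHIBITION}{all interneuron output (BC->GC, HC->GC) weights
#'     set to zero.}
#'   \item{GLOBAL_FB}{BC->GC edges redrawn with a global target pool and
#'     unchanged out-degree.}
#'   \item{NO_FACILITATION}{facilitation time constant of mossy-fiber
#'     outputs set to zero.}
#'   \item{FF_X2}{PP->BC (feedforward) weight doubled.}
#'   \item{TAU_SCALE}{inhibitory decay time constants multiplied by
#'     `factor` (0.5 to 5).}
#'   \item{PP_SCALE}{PP->GC weight multiplied by `factor` (> 0).}
#' }
#'
#' @param network a `dg_network` in the FULL state
#' @param condition condition name (see Details)
#' @param factor scale factor for `TAU_SCALE` / `PP_SCALE`
#' @return the modified network, with `condition` relabelled
#' @export
apply_condition <- function(network, condition, factor = NULL) {
  stopifnot(inherits(network, "dg_network"))
  if (network$condition != "FULL")
    stop("conditions must be applied to a FULL network")
  mf <- c("gc_bc", "gc_hc", "gc_mc")
  label <- condition
  net <- network
  if (condition == "FULL") {
  } else if (condition == "NO_FB") {
    net$edges$weight[net$edges$class %in% mf] <- 0
  } else if (condition == "NO_INHIBITION") {
    net$edges$weight[net$edges$class %in% c("bc_gc", "hc_gc")] <- 0
  } else if (condition == "GLOBAL_FB") {
    keep <- net$edges$class != "bc_gc"
    with_seed(derive_seed(net$seed_network, "rebuild"), {
      reb <- draw_edges(net, "bc_gc", pool_override = "global")
    })
    net$edges <- rbind(net$edges[keep, ], reb)
    rownames(net$edges) <- NULL
  } else if (condition == "NO_FACILITATION") {
    net$class_table$tau_facil[net$class_table$name %in% mf] <- 0
  } else if (condition == "FF_X2") {
    net$edges$weight[net$edges$class == "pp_bc"] <-
      2 * net$edges$weight[net$edges$class == "pp_bc"]
  } else if (condition == "TAU_SCALE") {
    stopifnot(!is.null(factor), factor >= 0.5, factor <= 5)
    inh <- net$class_table$e_rev < -50
    net$class_table$tau_decay[inh] <- net$class_table$tau_decay[inh] * factor
    label <- sprintf("TAU_SCALE_%g", factor)
  } else if (condition == "PP_SCALE") {
    stopifnot(!is.null(factor), factor > 0)
    net$edges$weight[net$edges$class == "pp_gc"] <-
      factor * net$edges$weight[net$edges$class == "pp_gc"]
    label <- sprintf("PP_SCALE_%g", factor)
  } else {
    stop("unknown condition: ", condition)
  }
  net$condition <- label
  net$cache <- new.env(parent = emptyenv())
  net
}

#' Audit the edge-table difference between two networks
#'
#' Compares two networks edge class by edge class and reports which
#' classes differ in weights, targets or class-level parameters. Used to
#' verify that [apply_condition()] changes only the declared parameters.
#'
#' @param a,b two `dg_network` objects built from the same configuration
#' @return data frame with one row per edge class and logical columns
#'   `weights_differ`, `wiring_differs`, plus `params_differ` per class row
#' @export
audit_conditions <- function(a, b) {
  stopifnot(identical(sort(unique(a$edges$class)),
                      sort(unique(b$edges$class))))
  cls <- sort(unique(a$edges$class))
  res <- lapply(cls, function(cn) {
    ea <- a$edges[a$edges$class == cn, ]
    eb <- b$edges[b$edges$class == cn, ]
    wiring <- !(nrow(ea) == nrow(eb) &&
                  all(ea$pre_unit == eb$pre_unit) &&
                  all(ea$post_cell == eb$post_cell))
    weights <- wiring || !all(ea$weight == eb$weight)
    pa <- a$class_table[a$class_table$name == cn,
                        c("tau_decay", "tau_facil", "U", "delay", "e_rev")]
    pb <- b$class_table[b$class_table$name == cn,
                        c("tau_decay", "tau_facil", "U", "delay", "e_rev")]
    data.frame(class = cn, wiring_differs = wiring,
               weights_differ = weights,
               params_differ = !isTRUE(all.equal(pa, pb,
                                                 check.attributes = FALSE)))
  })
  do.call(rbind, res)
}

#' @importFrom stats dnorm setNames
NULL
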