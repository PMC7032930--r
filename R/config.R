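#' Synapse specification
#'
#' One synaptic edge class: single-exponential conductance with
#' Tsodyks-Markram facilitation. `weight` is the conductance increment of an
#' isolated presynaptic spike; with facilitation the per-spike increment is
#' `weight * u / U`, where the utilisation `u` jumps by `U * (1 - u)` at each
#' spike and relaxes back with `tau_facil`. `tau_facil = 0` disables
#' facilitation (every increment equals `weight`).
#'
#' @param weight conductance increment (nS), >= 0
#' @param tau_decay conductance decay time constant (ms), > 0
#' @param tau_facil facilitation time constant (ms), >= 0; 0 disables
#' @param U baseline utilisation in (0, 1]; sets the maximal facilitation
#'   ratio 1/U
#' @param delay axonal + synaptic delay (ms), > 0
#' @param e_rev reversal potential (mV)
#' @return an object of class `dg_synapse_spec`
#' @export
synapse_spec <- function(weight, tau_decay, tau_facil = 0, U = 0.4,
                         delay = 1, e_rev = 0) {
  stopifnot(weight >= 0, tau_decay > 0, tau_facil >= 0,
            U > 0, U <= 1, delay > 0)
  structure(list(weight = weight, tau_decay = tau_decay,
                 tau_facil = tau_facil, U = U, delay = delay,
                 e_rev = e_rev),
            class = "dg_synapse_spec")
}

#' Connectivity rule
#'
#' Spatial wiring rule for one edge class: each presynaptic cell makes
#' `divergence` synapses onto distinct cells drawn from a target pool of
#' adjacent cells (`pool_extent` micrometres along the lamella, clipped at
#' the boundaries, never wrapped) or from the whole target population
#' (`pool_extent = "global"`). `profile = "gaussian"` weights targets by a
#' Gaussian of the given `sd` centred on the presynaptic position.
#'
#' @param divergence synaptic outputs per presynaptic cell
#' @param pool_extent pool width in micrometres, or `"global"`
#' @param profile `"uniform"` or `"gaussian"`
#' @param sd Gaussian SD (micrometres), required when `profile="gaussian"`
#' @return an object of class `dg_connectivity_rule`
#' @export
connectivity_rule <- function(divergence, pool_extent = "global",
                              profile = c("uniform", "gaussian"), sd = NULL) {
  profile <- match.arg(profile)
  stopifnot(divergence >= 1)
  if (!identical(pool_extent, "global")) stopifnot(pool_extent > 0)
  if (profile == "gaussian") stopifnot(!is.null(sd), sd > 0)
  structure(list(divergence = as.integer(divergence),
                 pool_extent = pool_extent, profile = profile, sd = sd),
            class = "dg_connectivity_rule")
}

# Reference (scale = 1) population sizes of the lamella model.
BASE_COUNTS <- c(pp = 400L, gc = 2000L, bc = 24L, hc = 24L, mc = 60L)

#' Tuned model defaults
#'
#' The tuned parameter tables of the lamella model: point-neuron
#' parameters per cell type (columns: capacitance C in pF, leak gL in nS,
#' leak reversal EL, spike threshold Vth, reset Vreset in mV, refractory
#' tref in ms, adaptation increment b in nS, adaptation decay tau_w in ms,
#' adaptation reversal E_adapt, initial potential Vinit), the synapse
#' table and the connectivity table. Start from these to build modified
#' configurations.
#'
#' @return `default_cell_params()` a matrix; the others named lists per
#'   edge class
#' @export
default_cell_params <- function() {
  rbind(
    gc = c(C = 120, gL = 4,  EL = -70, Vth = -45, Vreset = -70, tref = 4,
           b = 3,  tau_w = 150, E_adapt = -90, Vinit = -70, noise = 0),
    bc = c(C = 100, gL = 10, EL = -65, Vth = -21, Vreset = -67, tref = 3,
           b = 0,  tau_w = 30,  E_adapt = -90, Vinit = -65, noise = 120),
    hc = c(C = 60, gL = 5,  EL = -65, Vth = -34.3, Vreset = -67, tref = 3,
           b = 0,  tau_w = 30,  E_adapt = -90, Vinit = -65, noise = 85),
    mc = c(C = 150, gL = 5,  EL = -62, Vth = -45, Vreset = -58, tref = 3,
           b = 8,  tau_w = 150, E_adapt = -90, Vinit = -62, noise = 100))
}

# Mossy-fiber outputs (gc_*) carry the facilitation matched to the slice
# facilitation indices; inhibitory decay constants follow the base
# model's experimentally matched PSC kinetics.
#' @rdname default_cell_params
#' @export
default_synapse_table <- function() {
  list(
    pp_gc = synapse_spec(weight = 3.50, tau_decay = 5.5, delay = 1.5,
                         e_rev = 0),
    pp_bc = synapse_spec(weight = 2.50, tau_decay = 3.0, delay = 1.5,
                         e_rev = 0),
    gc_bc = synapse_spec(weight = 0.62, tau_decay = 6.0, tau_facil = 55,
                         U = 0.37, delay = 1.5, e_rev = 0),
    gc_hc = synapse_spec(weight = 0.268, tau_decay = 6.0, tau_facil = 55,
                         U = 0.37, delay = 1.5, e_rev = 0),
    gc_mc = synapse_spec(weight = 1.20, tau_decay = 6.0, tau_facil = 55,
                         U = 0.37, delay = 1.5, e_rev = 0),
    mc_bc = synapse_spec(weight = 0.10, tau_decay = 6.0, delay = 2.0,
                         e_rev = 0),
    mc_hc = synapse_spec(weight = 0.10, tau_decay = 6.0, delay = 2.0,
                         e_rev = 0),
    bc_gc = synapse_spec(weight = 18, tau_decay = 15, delay = 0.85,
                         e_rev = -75),
    hc_gc = synapse_spec(weight = 10, tau_decay = 20, delay = 1.6,
                         e_rev = -75))
}

# BC inputs/outputs are restricted to a ~600 um pool (local inhibition);
# HC inputs/outputs are spatially unrestricted (global inhibition).
#' @rdname default_cell_params
#' @export
default_connectivity_table <- function() {
  list(
    pp_gc = connectivity_rule(100, "global", "gaussian", sd = 1000),
    pp_bc = connectivity_rule(6, 600, "uniform"),
    gc_bc = connectivity_rule(4, 600, "uniform"),
    gc_hc = connectivity_rule(12, "global", "uniform"),
    gc_mc = connectivity_rule(3, 600, "uniform"),
    mc_bc = connectivity_rule(2, 600, "uniform"),
    mc_hc = connectivity_rule(2, "global", "uniform"),
    bc_gc = connectivity_rule(280, 600, "uniform"),
    hc_gc = connectivity_rule(1400, "global", "uniform"))
}

#' Network configuration
#'
#' Parameterises the dentate gyrus lamella circuit: 400 perforant-path
#' afferents, 2000 granule cells, 24 basket cells, 24 hilar
#' perforant-path-associated cells and 60 mossy cells on a 2 mm lamella at
#' `scale = 1`. `scale` down-scales all population counts proportionally
#' (rounded, minimum 1); wiring divergences shrink with the target
#' population and synaptic weights are compensated so the expected summed
#' conductance onto each cell is preserved. `keep_input = TRUE` retains the
#' full 400-afferent input space (and the input pattern geometry) while
#' scaling only the cellular populations.
#'
#' @param scale positive down-scaling ratio for desk runs
#' @param keep_input keep `n_pp` at its reference value when scaling
#' @param lamella_length lamella extent (micrometres)
#' @param dt integration step (ms)
#' @param duration default simulation duration (ms)
#' @param seed_network default wiring seed
#' @param synapse_table named list of [synapse_spec()] per edge class
#' @param connectivity_table named list of [connectivity_rule()] per edge
#'   class
#' @param cell_params matrix of point-neuron parameters per cell type
#' @param vth_jitter named numeric: half-width (mV) of the uniform
#'   per-cell spike-threshold spread per population
#' @return an object of class `dg_network_config`
#' @export
network_config <- function(scale = 1, keep_input = FALSE,
                           lamella_length = 2000, dt = 0.05, duration = 600,
                           seed_network = 1L,
                           synapse_table = default_synapse_table(),
                           connectivity_table = default_connectivity_table(),
                           cell_params = default_cell_params(),
                           vth_jitter = c(gc = 1, bc = 12, hc = 12,
                                          mc = 2.5)) {
  stopifnot(scale > 0, lamella_length > 0, dt > 0, duration > 0)
  counts <- vapply(BASE_COUNTS, function(n) max(1L, as.integer(round(n * scale))),
                   integer(1))
  if (keep_input) counts["pp"] <- BASE_COUNTS[["pp"]]
  stopifnot(all(counts > 0))
  stopifnot(identical(sort(names(synapse_table)),
                      sort(names(connectivity_table))))
  cfg <- structure(list(
    counts = counts, base_counts = BASE_COUNTS, scale = scale,
    lamella_length = lamella_length, dt = dt, duration = duration,
    seed_network = as.integer(seed_network),
    synapse_table = synapse_table,
    connectivity_table = connectivity_table,
    cell_params = cell_params, vth_jitter = vth_jitter),
    class = "dg_network_config")
  cfg
}

#' @export
print.dg_network_config <- function(x, ...) {
  cat("dentate lamella network configuration\n")
  cat(sprintf("  counts: PP %d | GC %d | BC %d | HC %d | MC %d (scale %.3g)\n",
              x$counts["pp"], x$counts["gc"], x$counts["bc"], x$counts["hc"],
              x$counts["mc"], x$scale))
  cat(sprintf("  lamella %g um, dt %g ms, duration %g ms\n",
              x$lamella_length, x$dt, x$duration))
  cat(sprintf("  edge classes: %s\n",
              paste(names(x$synapse_table), collapse = ", ")))
  invisible(x)
}

# population of the pre/post side of an edge class ("pp_gc" -> pp, gc)
edge_populations <- function(class_name) {
  parts <- strsplit(class_name, "_", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2)
  list(pre = parts[1], post = parts[2])
}

#' Write / read a network configuration as JSON
#'
#' Flat JSON mirror of the configuration so that every run can store the
#' resolved parameters next to its results.
#'
#' @param config a `dg_network_config`
#' @param path file path
#' @return `read_network_config` returns a `dg_network_config`
#' @export
write_network_config <- function(config, path) {
  ser <- list(
    counts = as.list(config$counts), scale = config$scale,
    keep_input = config$counts[["pp"]] == config$base_counts[["pp"]] &&
      config$scale != 1,
    lamella_length = config$lamella_length, dt = config$dt,
    duration = config$duration, seed_network = config$seed_network,
    vth_jitter = as.list(config$vth_jitter),
    cell_params = apply(config$cell_params, 1, as.list, simplify = FALSE),
    synapse_table = lapply(config$synapse_table, unclass),
    connectivity_table = lapply(config$connectivity_table, unclass))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- lapply(ser$synapse_table, function(s)
    synapse_spec(s$weight, s$tau_decay, s$tau_facil, s$U, s$delay, s$e_rev))
  con <- lapply(ser$connectivity_table, function(s)
    connectivity_rule(s$divergence,
                      if (identical(s$pool_extent, "global")) "global"
                      else as.numeric(s$pool_extent),
                      s$profile, sd = s$sd))
  cp <- do.call(rbind, lapply(ser$cell_params, unlist))
  cfg <- network_config(scale = ser$scale,
                        keep_input = isTRUE(ser$keep_input),
                        lamella_length = ser$lamella_length, dt = ser$dt,
                        duration = ser$duration,
                        seed_network = ser$seed_network,
                        synapse_table = syn, connectivity_table = con,
                        cell_params = cp,
                        vth_jitter = unlist(ser$vth_jitter))
  cfg
}
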