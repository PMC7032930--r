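#' Conductance response of a facilitating synapse
#'
#' Closed-form time course of a single Tsodyks-Markram facilitating
#' synapse: each presynaptic spike increments the conductance by
#' `weight * u / U`, where the utilisation `u` jumps by `U * (1 - u)` per
#' spike and decays back with `tau_facil` between spikes; the conductance
#' itself decays exponentially with `tau_decay`. With `tau_facil = 0`
#' every increment equals `weight`, so a single spike produces a single
#' exponential of peak `weight`.
#'
#' @param spike_times sorted presynaptic spike times (ms)
#' @param spec a [synapse_spec()]
#' @param dt sampling step of the returned time course (ms)
#' @param t_max end of the returned time course (ms)
#' @return list with `time`, `g` (conductance trace, nS) and `increments`
#'   (per-spike conductance increments, nS)
#' @export
tm_synapse_response <- function(spike_times, spec, dt = 0.1,
                                t_max = max(spike_times) + 5 * spec$tau_decay) {
  stopifnot(inherits(spec, "dg_synapse_spec"))
  if (is.unsorted(spike_times, strictly = FALSE))
    stop("spike_times must be sorted")
  inc <- tm_increments(as.numeric(spike_times), spec$weight,
                       spec$tau_facil, spec$U)
  time <- seq(0, t_max, by = dt)
  g <- numeric(length(time))
  for (k in seq_along(spike_times)) {
    on <- time >= spike_times[k]
    g[on] <- g[on] + inc[k] * exp(-(time[on] - spike_times[k]) / spec$tau_decay)
  }
  list(time = time, g = g, increments = as.numeric(inc))
}

#' Run one network simulation
#'
#' Integrates the network for `duration` ms under perforant-path drive
#' and/or direct current injections. The result is bit-reproducible for a
#' fixed `(network, drive, dt)`. The model has no spontaneous activity:
#' with zero drive no cell fires.
#'
#' @param network a `dg_network`
#' @param drive list of PP spike-time vectors (ms); element `i` drives
#'   afferent `i`. Shorter lists are padded with silence; spikes beyond
#'   `duration` are dropped with a warning.
#' @param duration simulated time (ms)
#' @param dt integration step (ms); steps above 0.2 ms are refused
#' @param injections data frame / matrix with columns `cell` (1-based GC
#'   index), `start`, `duration`, `amplitude` (pA) for somatic current
#'   pulses
#' @param probes 1-based GC indices held in voltage clamp at `clamp_v`;
#'   their synaptic currents are recorded every step
#' @param clamp_v probe holding potential (mV)
#' @param disable_probe_excitation zero all excitatory synapses onto the
#'   probes (the tuning protocols measure pure IPSCs)
#' @param noise_seed seed of the membrane-noise stream (per-type noise
#'   amplitudes come from the cell-parameter table); the default derives
#'   it from the wiring seed, so repeated identical calls reproduce
#'   bit-identical results
#' @return an object of class `dg_sim_result`: `spikes` (data frame
#'   `population`, `cell`, `time`), probe traces, and run metadata
#' @export
run_simulation <- function(network, drive = NULL,
                           duration = network$config$duration,
                           dt = network$config$dt,
                           injections = NULL, probes = NULL,
                           clamp_v = 0, disable_probe_excitation = TRUE,
                           noise_seed = NULL) {
  stopifnot(inherits(network, "dg_network"))
  if (dt > 0.2)
    stop("dt = ", dt, " ms is numerically unsafe for this model; ",
         "use dt <= 0.2 ms")
  n_pp <- network$counts[["pp"]]
  n_cells <- sum(network$counts[c("gc", "bc", "hc", "mc")])

  pp_spikes <- rep(list(numeric(0)), n_pp)
  if (!is.null(drive)) {
    if (length(drive) > n_pp)
      stop("drive indexes afferent ", length(drive),
           " but the network has only ", n_pp, " PP afferents")
    trunc <- FALSE
    for (i in seq_along(drive)) {
      st <- as.numeric(drive[[i]])
      if (any(st >= duration)) trunc <- TRUE
      pp_spikes[[i]] <- st[st < duration]
    }
    if (trunc) warning("drive extends beyond `duration`; spikes truncated")
  }

  edges <- network$edges
  if (!is.null(probes) && disable_probe_excitation) {
    exc_cls <- network$class_table$name[network$class_table$e_rev > -50]
    probe_cells <- network$offsets[["gc"]] + probes - 1L
    kill <- edges$class %in% exc_cls & edges$post_cell %in% probe_cells
    edges$weight[kill] <- 0
  }

  cls <- network$class_table
  n_units <- n_pp + n_cells
  # the CSR layout depends only on the wiring, not on weights; reuse it
  # across calls on the same network
  cache <- network$cache
  if (is.null(cache) || is.null(cache$ord) ||
      !identical(cache$n_edges, nrow(edges))) {
    ord <- order(edges$pre_unit, method = "radix")
    ptr <- c(0L, cumsum(tabulate(edges$pre_unit + 1L, nbins = n_units)))
    cls_idx <- match(edges$class, cls$name) - 1L
    if (!is.null(cache)) {
      cache$ord <- ord
      cache$ptr <- ptr
      cache$cls_idx <- cls_idx
      cache$post_ord <- as.integer(edges$post_cell[ord])
      cache$cls_ord <- as.integer(cls_idx[ord])
      cache$n_edges <- nrow(edges)
    }
  } else {
    ord <- cache$ord
    ptr <- cache$ptr
  }
  post_ord <- if (!is.null(cache) && !is.null(cache$post_ord))
    cache$post_ord else as.integer(edges$post_cell[ord])
  cls_ord <- if (!is.null(cache) && !is.null(cache$cls_ord))
    cache$cls_ord else {
      cls_idx <- match(edges$class, cls$name) - 1L
      as.integer(cls_idx[ord])
    }

  inj <- matrix(0, 0, 4)
  if (!is.null(injections)) {
    injections <- as.data.frame(injections)
    inj <- cbind(network$offsets[["gc"]] + injections$cell - 1L,
                 injections$start, injections$duration,
                 injections$amplitude)
  }
  clamp_cells <- if (is.null(probes)) integer(0)
                 else as.integer(network$offsets[["gc"]] + probes - 1L)
  if (is.null(noise_seed))
    noise_seed <- derive_seed(network$seed_network, "network")
  cp <- network$config$cell_params
  noise_col <- if ("noise" %in% colnames(cp)) cp[, "noise"] else rep(0, 4)

  res <- sim_core(
    n_pp = n_pp, n_cells = n_cells,
    cell_type = as.integer(network$cell_type),
    type_params = cp[, colnames(cp) != "noise", drop = FALSE],
    cell_vth = network$cell_vth,
    edge_ptr = as.integer(ptr),
    edge_post = post_ord,
    edge_class = cls_ord,
    edge_weight = as.numeric(edges$weight[ord]),
    cls_tau = cls$tau_decay, cls_tau_facil = cls$tau_facil,
    cls_U = cls$U, cls_delay = cls$delay, cls_erev = cls$e_rev,
    pp_spikes = pp_spikes, inj = inj,
    clamp_cells = clamp_cells, clamp_v = clamp_v,
    record_probe = length(clamp_cells) > 0,
    noise_sd = as.numeric(noise_col),
    noise_seed = as.integer(noise_seed %% 2147483647),
    dt = dt, duration = duration)

  pops <- c("gc", "bc", "hc", "mc")
  cuts <- c(network$offsets[["bc"]], network$offsets[["hc"]],
            network$offsets[["mc"]], n_cells)
  pop_of <- pops[findInterval(res$spike_cell, c(0, cuts), rightmost.closed = FALSE)]
  cell_in_pop <- res$spike_cell - c(gc = 0L, bc = cuts[1], hc = cuts[2],
                                    mc = cuts[3])[pop_of] + 1L
  spikes <- data.frame(population = pop_of, cell = as.integer(cell_in_pop),
                       time = res$spike_time)

  structure(list(
    spikes = spikes,
    probe_ipsc = res$probe_ipsc, probe_epsc = res$probe_epsc,
    probes = probes, clamp_v = clamp_v,
    time = seq(0, by = dt, length.out = res$n_steps),
    counts = network$counts, condition = network$condition,
    duration = duration, dt = dt,
    seed_network = network$seed_network),
    class = "dg_sim_result")
}

#' @export
print.dg_sim_result <- function(x, ...) {
  cat(sprintf("simulation result [%s], %g ms at dt %g ms\n",
              x$condition, x$duration, x$dt))
  for (p in c("gc", "bc", "hc", "mc")) {
    n <- sum(x$spikes$population == p)
    cat(sprintf("  %s: %d spikes from %d/%d cells\n", toupper(p), n,
                length(unique(x$spikes$cell[x$spikes$population == p])),
                x$counts[[p]]))
  }
  invisible(x)
}

#' Spike table input/output
#'
#' Tab-separated spike format shared by the simulator and the surrogate
#' generator: columns `population`, `cell_id` (0-based), `spike_time_ms`.
#' A JSON manifest with the run metadata is written alongside when
#' `manifest = TRUE`.
#'
#' @param result a `dg_sim_result`
#' @param path output TSV path
#' @param manifest also write `<path>.json` with seeds/condition/duration
#' @return `read_spikes` returns a `dg_sim_result` (spikes and metadata
#'   only, no probe traces)
#' @export
write_spikes <- function(result, path, manifest = TRUE) {
  df <- data.frame(population = result$spikes$population,
                   cell_id = result$spikes$cell - 1L,
                   spike_time_ms = result$spikes$time)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (manifest) {
    meta <- list(condition = result$condition, duration = result$duration,
                 dt = result$dt, seed_network = result$seed_network,
                 counts = as.list(result$counts))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @param counts named population sizes (required if no manifest is found)
#' @export
read_spikes <- function(path, counts = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "numeric"))
  mp <- paste0(path, ".json")
  meta <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
          else list(condition = NA_character_, duration = NA_real_,
                    dt = NA_real_, seed_network = NA_integer_,
                    counts = counts)
  if (is.null(meta$counts)) stop("population counts unavailable; pass `counts`")
  structure(list(
    spikes = data.frame(population = df$population,
                        cell = df$cell_id + 1L, time = df$spike_time_ms),
    probe_ipsc = NULL, probe_epsc = NULL, probes = NULL,
    time = NULL, counts = unlist(meta$counts), condition = meta$condition,
    duration = meta$duration, dt = meta$dt,
    seed_network = meta$seed_network),
    class = "dg_sim_result")
}
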