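#' Experiment plan
#'
#' Declares a full in-silico experiment: conditions crossed with input
#' modulation frequencies, replicated over independently wired network
#' seeds, each run over all patterns of a family. Within one replicate
#' the same input family is fed to every condition (paired design), so
#' isolated effects can be computed pair by pair.
#'
#' @param conditions character vector of condition names (see
#'   [apply_condition()]); `TAU_SCALE`/`PP_SCALE` may carry a factor as
#'   `"TAU_SCALE:2"`
#' @param frequencies input modulation frequencies (Hz)
#' @param n_seeds number of network replicates
#' @param base_seed seed from which the replicate seeds are enumerated
#' @param network_config a [network_config()]
#' @param input_config an [input_config()] (its `mod_freq` is overridden
#'   per frequency level)
#' @param measures similarity measures to compute
#' @param window analysis window length (ms); the full duration by default
#' @param with_self include self-pairs
#' @return object of class `dg_experiment_plan`
#' @export
experiment_plan <- function(conditions = c("FULL", "NO_FB", "NO_INHIBITION"),
                            frequencies = c(10, 30), n_seeds = 7,
                            base_seed = 1L,
                            network_config = dgsep::network_config(),
                            input_config = dgsep::input_config(),
                            measures = "pearson", window = NULL,
                            with_self = TRUE) {
  stopifnot(n_seeds >= 1, length(conditions) >= 1, length(frequencies) >= 1)
  seeds <- as.integer(base_seed) + 7919L * (seq_len(n_seeds) - 1L)
  structure(list(conditions = conditions, frequencies = frequencies,
                 seeds = seeds, network_config = network_config,
                 input_config = input_config, measures = measures,
                 window = window, with_self = with_self),
            class = "dg_experiment_plan")
}

parse_condition <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  list(name = parts[1],
       factor = if (length(parts) > 1) as.numeric(parts[2]) else NULL)
}

#' Run an experiment plan
#'
#' For every (seed, frequency, pattern, condition) one simulation is run;
#' per (seed, frequency, condition) the pairwise similarity table and its
#' separation summary are computed, and isolated effects versus the first
#' condition (normally `FULL`) are attached. With `outdir` set, spike
#' tables, pair tables and a JSON manifest are persisted and finished
#' runs are resumed from disk on a rerun.
#'
#' @param plan a [experiment_plan()]
#' @param outdir results directory (optional)
#' @param progress print per-run progress
#' @return object of class `dg_experiment`: `summary` data frame (one row
#'   per seed x condition x frequency x measure), `pairs` (nested list),
#'   `plan`
#' @export
run_experiment <- function(plan, outdir = NULL, progress = FALSE) {
  stopifnot(inherits(plan, "dg_experiment_plan"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  summ <- list()
  pairs_store <- list()
  for (si in seq_along(plan$seeds)) {
    seed <- plan$seeds[si]
    net_full <- build_network(plan$network_config, seed = seed)
    for (fr in plan$frequencies) {
      icfg <- plan$input_config
      icfg$mod_freq <- fr
      icfg$seed_input <- derive_seed(seed, "input")
      family <- generate_pattern_family(icfg)
      for (cond in plan$conditions) {
        pc <- parse_condition(cond)
        net <- apply_condition(net_full, pc$name, pc$factor)
        key <- sprintf("seed%d_f%g_%s", seed, fr, net$condition)
        results <- run_family(net, family, outdir, key, progress)
        for (ms in plan$measures) {
          prs <- all_pairs(results, family, measure = ms,
                           window = plan$window,
                           with_self = plan$with_self)
          curve <- binwise_curve(prs)
          act <- vapply(results, function(r)
            activity_metrics(r)$active_fraction, numeric(1))
          pairs_store[[key]][[ms]] <- prs
          summ[[length(summ) + 1]] <- data.frame(
            seed = seed, frequency = fr, condition = net$condition,
            measure = ms,
            mean_delta_rout = mean_delta_rout_full(curve),
            band_mean_rout = band_mean(prs, "r_out"),
            active_fraction = mean(act))
          if (!is.null(outdir)) {
            write.table(prs, file.path(outdir, sprintf("pairs_%s_%s.tsv",
                                                       key, ms)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
          }
        }
      }
    }
  }
  summary <- do.call(rbind, summ)

  # isolated effects versus the first (reference) condition
  iso <- list()
  ref <- parse_condition(plan$conditions[1])$name
  for (key in names(pairs_store)) {
    for (ms in plan$measures) {
      info <- strsplit(key, "_", fixed = TRUE)[[1]]
      cond <- paste(info[-(1:2)], collapse = "_")
      if (cond == ref) next
      ref_key <- sprintf("%s_%s_%s", info[1], info[2], ref)
      if (is.null(pairs_store[[ref_key]])) next
      d <- isolated_effect(pairs_store[[ref_key]][[ms]],
                           pairs_store[[key]][[ms]])
      iso[[length(iso) + 1]] <- data.frame(
        seed = as.integer(sub("seed", "", info[1])),
        frequency = as.numeric(sub("f", "", info[2])),
        condition = cond, measure = ms,
        mean_delta_isolated = mean_delta_isolated(d),
        band_delta_isolated = band_mean(d, "delta"))
    }
  }
  out <- structure(list(summary = summary,
                        isolated = if (length(iso)) do.call(rbind, iso)
                                   else NULL,
                        pairs = pairs_store, plan = plan),
                   class = "dg_experiment")
  if (!is.null(outdir)) {
    write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(out$isolated))
      write.table(out$isolated, file.path(outdir, "isolated.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(seeds = plan$seeds, conditions = plan$conditions,
                     frequencies = plan$frequencies,
                     measures = plan$measures,
                     with_self = plan$with_self,
                     input_config = unclass(plan$input_config))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_network_config(plan$network_config,
                         file.path(outdir, "network_config.json"))
  }
  out
}

# run (or resume from disk) the 25 pattern simulations of one condition
run_family <- function(net, family, outdir, key, progress = FALSE) {
  lapply(seq_len(family$cfg$n_patterns), function(p) {
    path <- if (!is.null(outdir))
      file.path(outdir, sprintf("spikes_%s_p%02d.tsv", key, p)) else NULL
    if (!is.null(path) && file.exists(path) &&
        file.exists(paste0(path, ".json"))) {
      return(read_spikes(path))
    }
    if (progress) message(key, " pattern ", p)
    res <- run_simulation(net, drive = pattern_drive(family, p))
    if (!is.null(path)) write_spikes(res, path)
    res
  })
}

#' @export
print.dg_experiment <- function(x, ...) {
  cat("in-silico experiment:",
      length(x$plan$seeds), "seeds x",
      length(x$plan$conditions), "conditions x",
      length(x$plan$frequencies), "frequencies\n")
  agg <- aggregate(mean_delta_rout ~ condition + frequency + measure,
                   x$summary, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Robustness scan
#'
#' Runs a full analysis per level of one axis and reports each level's
#' summary against the tuned baseline: `axis = "tau"` scales the
#' inhibitory decay constants (`TAU_SCALE`), `"pp"` the PP->GC weight
#' (`PP_SCALE`), `"freq"` the input modulation frequency.
#'
#' @param plan a [experiment_plan()] (its `conditions`/`frequencies` are
#'   reused; for `tau`/`pp` the conditions are replaced by scaled
#'   variants plus the baseline)
#' @param axis `"tau"`, `"pp"` or `"freq"`
#' @param levels numeric axis levels (scale factors, or Hz for `freq`)
#' @param ... passed to [run_experiment()]
#' @return named list of `dg_experiment` summaries, one per level
#' @export
scan_axis <- function(plan, axis = c("tau", "pp", "freq"), levels, ...) {
  axis <- match.arg(axis)
  out <- list()
  for (lv in levels) {
    p <- plan
    if (axis == "tau") {
      p$conditions <- ifelse(plan$conditions == "FULL" & lv != 1,
                             sprintf("TAU_SCALE:%g", lv), plan$conditions)
    } else if (axis == "pp") {
      p$conditions <- ifelse(plan$conditions == "FULL" & lv != 1,
                             sprintf("PP_SCALE:%g", lv), plan$conditions)
    } else {
      p$frequencies <- lv
    }
    out[[as.character(lv)]] <- run_experiment(p, ...)$summary
  }
  out
}

#' @importFrom stats aggregate
NULL
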