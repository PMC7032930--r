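#' Focal granule-cell activation
#'
#' Tuning-phase protocol: the `n_active` granule cells nearest to
#' `position` are driven to spike by a suprathreshold somatic current
#' pulse (default 12 ms: the optogenetic pulses lasted 20 ms, but only
#' spikes preceding the evoked IPSC recruit it, so the effective
#' recruiting burst is shorter), while a
#' probe granule cell is held in voltage clamp at 0 mV with its excitatory
#' inputs disabled. Returned is the probe's compound feedback IPSC trace
#' and its baseline-subtracted peak (the maximum clamp current within
#' 100 ms of pulse onset).
#'
#' @param network a `dg_network`
#' @param position activation centre on the lamella (micrometres)
#' @param n_active number of granule cells forced to spike
#' @param probe 1-based GC index of the probe cell; defaults to the cell
#'   nearest the lamella centre
#' @param pulse_ms pulse width (ms)
#' @param amplitude pulse current (pA)
#' @param t_on pulse onset (ms)
#' @param duration simulated time (ms)
#' @param n_trials noise realisations averaged per stimulation
#' @return list `trace` (pA), `time` (ms), `peak` (pA, trial-averaged),
#'   `probe`,
#'   `n_active`, `position`
#' @export
focal_activation <- function(network, position, n_active,
                             probe = NULL, pulse_ms = 12, amplitude = 4000,
                             t_on = 20, duration = 160, n_trials = 3) {
  L <- network$config$lamella_length
  if (position < 0 || position > L)
    stop("position outside the lamella [0, ", L, "]")
  gc_pos <- network$positions$gc
  if (is.null(probe)) probe <- which.min(abs(gc_pos - L / 2))
  pool <- setdiff(order(abs(gc_pos - position)), probe)[seq_len(n_active)]
  inj <- if (n_active > 0)
    data.frame(cell = pool, start = t_on, duration = pulse_ms,
               amplitude = amplitude)
  else NULL
  # stimulations delivered in triplicate (independent noise realisations)
  # and averaged, as in the slice protocol
  runs <- lapply(seq_len(n_trials), function(tr)
    run_simulation(network, drive = NULL, duration = duration,
                   injections = inj, probes = probe,
                   clamp_v = 0, disable_probe_excitation = TRUE,
                   noise_seed = derive_seed(network$seed_network,
                                            "network") + 977L * tr))
  res <- runs[[1]]
  i_on <- findInterval(t_on, res$time)
  i_end <- findInterval(min(t_on + 100, duration - res$dt), res$time)
  peak <- mean(vapply(runs, function(r) {
    trace <- r$probe_ipsc[, 1]
    max(trace[i_on:i_end] - trace[i_on])
  }, numeric(1)))
  list(trace = res$probe_ipsc[, 1], time = res$time, peak = peak,
       probe = probe, n_active = n_active, position = position,
       result = res)
}

#' Recruitment curve of net feedback inhibition
#'
#' Sweeps the activated granule-cell fraction at a stimulation site and
#' records the probe's peak feedback IPSC. `site = "local"` activates
#' around the probe; `site = "remote"` 800 um along the lamella from it
#' (the experimental remote definition), clipped to the lamella.
#'
#' @param network a `dg_network`
#' @param site `"local"` or `"remote"`
#' @param fractions active GC fractions to test (percent)
#' @param probe probe GC index; default as in [focal_activation()]
#' @param remote_offset distance of remote activation (micrometres)
#' @param ... passed to [focal_activation()]
#' @return object of class `dg_recruitment`: data frame `fraction`
#'   (percent), `ipsc` (pA, raw peak), `norm` (percent of the curve
#'   maximum), plus attributes
#' @export
recruitment_curve <- function(network, site = c("local", "remote"),
                              fractions = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5,
                                            6, 8),
                              probe = NULL, remote_offset = 800, ...) {
  site <- match.arg(site)
  L <- network$config$lamella_length
  gc_pos <- network$positions$gc
  if (is.null(probe)) probe <- which.min(abs(gc_pos - L / 2))
  pos <- gc_pos[probe]
  if (site == "remote") {
    pos <- if (pos + remote_offset <= L) pos + remote_offset
           else pos - remote_offset
    pos <- min(max(pos, 0), L)
  }
  n_gc <- network$counts[["gc"]]
  peaks <- vapply(fractions, function(f) {
    n <- max(1L, round(n_gc * f / 100))
    focal_activation(network, pos, n, probe = probe, ...)$peak
  }, numeric(1))
  out <- data.frame(fraction = fractions, ipsc = peaks,
                    norm = if (max(peaks) > 0) 100 * peaks / max(peaks)
                           else peaks)
  attr(out, "site") <- site
  attr(out, "probe") <- probe
  class(out) <- c("dg_recruitment", "data.frame")
  out
}

#' Half-maximal recruitment fraction
#'
#' Active granule-cell fraction at which a recruitment curve crosses the
#' half-maximal IPSC, by linear interpolation between the bracketing
#' measured points. IPSC values are in the normalised percent scale (100 =
#' the probe cell's maximal IPSC over space and power), so half-maximal
#' means 50% regardless of where the individual curve saturates; pass
#' `reference = max(curve$ipsc)` for a raw single-site curve.
#'
#' @param curve a `dg_recruitment` (or any data frame with `fraction` and
#'   an IPSC column)
#' @param column IPSC column to use
#' @param reference the value that counts as the maximal IPSC (100 for
#'   normalised curves)
#' @return half-maximal active fraction (percent)
#' @export
recruitment_halfmax <- function(curve, column = "norm", reference = 100) {
  y <- curve[[column]]
  x <- curve$fraction
  stopifnot(length(x) >= 2)
  half <- reference / 2
  above <- which(y >= half)
  if (!length(above))
    stop("curve never reaches 50% of the maximal IPSC (unsaturated)")
  k <- above[1]
  if (k == 1) return(x[1])
  x[k - 1] + (half - y[k - 1]) * (x[k] - x[k - 1]) / (y[k] - y[k - 1])
}

#' Local and remote recruitment analysis
#'
#' Runs the local and remote recruitment curves of one probe cell,
#' normalises both to the joint maximum over space and power (the
#' experimental normalisation, so all values are below or equal to 100%)
#' and interpolates the half-maximal active fractions.
#'
#' @param network a `dg_network`
#' @param fractions active GC fractions to test (percent)
#' @param probe probe GC index; alternatively `probe_positions` gives
#'   several probe cells (by lamella position) whose half-max estimates
#'   are averaged, emulating the experimental per-cell analysis
#' @param probe_positions optional probe positions (micrometres)
#' @param ... passed to [recruitment_curve()]
#' @return list `local`, `remote` (normalised `dg_recruitment` tables of
#'   the first probe), `halfmax_local`, `halfmax_remote` (percent active
#'   GCs, averaged over probes), `saturated_remote` (remote plateau,
#'   percent of global maximum), `per_probe`
#' @export
recruitment_analysis <- function(network,
                                 fractions = c(0.5, 1, 1.5, 2, 2.5, 3, 4,
                                               5, 6, 8),
                                 probe = NULL, probe_positions = NULL,
                                 ...) {
  probes <- if (!is.null(probe_positions)) {
    vapply(probe_positions, function(pp)
      which.min(abs(network$positions$gc - pp)), integer(1))
  } else if (is.null(probe)) {
    which.min(abs(network$positions$gc -
                    network$config$lamella_length / 2))
  } else probe
  per <- lapply(probes, function(pb) {
    loc <- recruitment_curve(network, "local", fractions, probe = pb, ...)
    rem <- recruitment_curve(network, "remote", fractions, probe = pb, ...)
    gmax <- max(loc$ipsc, rem$ipsc)
    loc$norm <- 100 * loc$ipsc / gmax
    rem$norm <- 100 * rem$ipsc / gmax
    hl <- tryCatch(recruitment_halfmax(loc), error = function(e) NA_real_)
    hr <- tryCatch(recruitment_halfmax(rem), error = function(e) NA_real_)
    list(local = loc, remote = rem, halfmax_local = hl,
         halfmax_remote = hr, saturated_remote = max(rem$norm))
  })
  # probes whose curves never saturate are excluded (with a warning), as
  # such cells would not have entered the experimental sample
  bad <- vapply(per, function(x)
    is.na(x$halfmax_local) || is.na(x$halfmax_remote), logical(1))
  if (all(bad)) stop("no probe yielded saturating recruitment curves")
  if (any(bad)) {
    warning(sum(bad), " probe(s) with unsaturated curves excluded")
    per <- per[!bad]
  }
  list(local = per[[1]]$local, remote = per[[1]]$remote,
       halfmax_local = mean(vapply(per, `[[`, 0, "halfmax_local")),
       halfmax_remote = mean(vapply(per, `[[`, 0, "halfmax_remote")),
       n_probes = length(per),
       saturated_remote = mean(vapply(per, `[[`, 0, "saturated_remote")),
       per_probe = per)
}

#' Spatial profile of net feedback inhibition
#'
#' Activates fixed granule-cell populations at positions along the
#' lamella (100 um grid by default) at several activation strengths and
#' maps the probe's peak IPSC, normalised to the probe's global maximum
#' over space and strength (so the map's maximum is 100% at exactly one
#' point).
#'
#' @param network a `dg_network`
#' @param positions activation centres (micrometres)
#' @param fractions activated GC fractions (percent), the "powers" of the
#'   sweep
#' @param probe probe GC index
#' @param ... passed to [focal_activation()]
#' @return matrix `length(positions) x length(fractions)` of normalised
#'   IPSC (percent), with positions as rownames
#' @export
spatial_profile <- function(network,
                            positions = seq(0, network$config$lamella_length,
                                            by = 100),
                            fractions = c(1, 2, 4), probe = NULL, ...) {
  L <- network$config$lamella_length
  gc_pos <- network$positions$gc
  if (is.null(probe)) probe <- which.min(abs(gc_pos - L / 2))
  n_gc <- network$counts[["gc"]]
  m <- outer(positions, fractions, Vectorize(function(pos, f) {
    focal_activation(network, pos, max(1L, round(n_gc * f / 100)),
                     probe = probe, ...)$peak
  }))
  if (max(m) > 0) m <- 100 * m / max(m)
  rownames(m) <- positions
  colnames(m) <- fractions
  m
}

#' Facilitation of the compound feedback IPSC
#'
#' Train-stimulation protocol: a small granule-cell pool near the probe
#' is driven to spike synchronously by ten brief current pulses at the
#' given frequency (emulating minimal antidromic stimulation); the
#' probe's compound IPSC peak is measured after each pulse
#' (baseline-subtracted within each inter-pulse interval) and the
#' facilitation index is the mean of the last three peaks over the first.
#'
#' @param network a `dg_network`
#' @param freq stimulation frequency (Hz)
#' @param n_pulses pulses per train
#' @param pool_frac stimulated GC fraction (percent); `NULL` (default)
#'   calibrates the pool per probe so the first IPSC is reliable but far
#'   from saturation, emulating the per-slice adjustment of the
#'   stimulation power to the minimal level yielding reliable responses
#' @param probe probe GC index
#' @param pulse_ms pulse width (ms)
#' @param amplitude pulse current (pA); strong and brief, emulating
#'   antidromic axonal stimulation that evoked inhibition cannot veto
#' @param stagger_ms conduction-delay spread of the antidromic volley
#'   (ms); onsets are staggered evenly across the pool
#' @param n_trials noise realisations averaged per train (the slice
#'   protocol delivered trains in triplicate)
#' @param target_first calibration target: first-volley IPSC as a
#'   fraction of the probe's single-volley saturation
#' @return object of class `dg_facilitation`: `freq`, `psc_peaks` (10
#'   amplitudes, pA) and `facilitation_index`
#' @export
facilitation_protocol <- function(network, freq, n_pulses = 10,
                                  pool_frac = NULL, probe = NULL,
                                  pulse_ms = 2, amplitude = 5000,
                                  stagger_ms = 4, n_trials = 3,
                                  target_first = 0.25) {
  L <- network$config$lamella_length
  gc_pos <- network$positions$gc
  if (is.null(probe)) probe <- which.min(abs(gc_pos - L / 2))
  n_gc <- network$counts[["gc"]]
  n_pool <- if (is.null(pool_frac)) {
    calibrate_pool(network, probe, target_first = target_first,
                   pulse_ms = pulse_ms, amplitude = amplitude,
                   stagger_ms = stagger_ms)
  } else max(1L, round(n_gc * pool_frac / 100))
  pool <- setdiff(order(abs(gc_pos - gc_pos[probe])), probe)[seq_len(n_pool)]
  isi <- 1000 / freq
  t0 <- 20
  onsets <- t0 + (seq_len(n_pulses) - 1) * isi
  offsets <- seq(0, stagger_ms, length.out = n_pool)
  inj <- data.frame(cell = rep(pool, n_pulses),
                    start = rep(onsets, each = n_pool) + rep(offsets, n_pulses),
                    duration = pulse_ms, amplitude = amplitude)
  duration <- max(onsets) + min(isi, 100) + 20
  win <- min(isi, 100)
  # Trains are delivered in triplicate (independent noise realisations)
  # and the peak sequences averaged, as in the slice recordings. The
  # amplitudes that enter the facilitation index (pulses 1, 8, 9, 10)
  # are measured by omission differencing: the same train is resimulated
  # with pulse k omitted, which (the trajectory being deterministic per
  # noise seed) yields the exact summation baseline for window k, so
  # amplitudes are unbiased even when compound IPSCs ride on the decay
  # of their predecessors. Intermediate pulses are reported from a
  # local-slope extrapolation of the riding baseline.
  run_train <- function(keep, tr) {
    sel <- rep(keep, each = n_pool)
    res <- run_simulation(network, drive = NULL, duration = duration,
                          injections = inj[sel, ], probes = probe,
                          clamp_v = 0, disable_probe_excitation = TRUE,
                          noise_seed = derive_seed(network$seed_network,
                                                   "network") + 131L * tr)
    res
  }
  key_pulses <- intersect(c(1L, n_pulses - 2L, n_pulses - 1L, n_pulses),
                          seq_len(n_pulses))
  trial_peaks <- vapply(seq_len(n_trials), function(tr) {
    full <- run_train(rep(TRUE, n_pulses), tr)
    trace <- full$probe_ipsc[, 1]
    amps <- vapply(seq_len(n_pulses), function(k) {
      on <- onsets[k]
      i0 <- findInterval(on, full$time)
      i1 <- findInterval(min(on + win, duration - full$dt), full$time)
      tt <- full$time[i0:i1] - on
      tau_loc <- local_decay_tau(trace, full$time, on)
      max(trace[i0:i1] - trace[i0] * exp(-tt / tau_loc))
    }, numeric(1))
    for (k in setdiff(key_pulses, 1L)) {
      omit <- run_train(seq_len(n_pulses) != k, tr)
      on <- onsets[k]
      i0 <- findInterval(on, full$time)
      i1 <- findInterval(min(on + win, duration - full$dt), full$time)
      amps[k] <- max(trace[i0:i1] - omit$probe_ipsc[i0:i1, 1])
    }
    amps
  }, numeric(n_pulses))
  peaks <- rowMeans(trial_peaks)
  if (peaks[1] <= 1e-9)
    stop("undetectable first IPSC peak; increase pool_frac")
  structure(list(freq = freq, psc_peaks = peaks,
                 facilitation_index = facilitation_index(peaks),
                 probe = probe, pool = pool),
            class = "dg_facilitation")
}

#' @export
print.dg_facilitation <- function(x, ...) {
  cat(sprintf("feedback IPSC train at %g Hz: facilitation index %.3f\n",
              x$freq, x$facilitation_index))
  cat("  peaks (pA):", paste(sprintf("%.1f", x$psc_peaks), collapse = " "),
      "\n")
  invisible(x)
}


#' Facilitation index of a peak sequence
#'
#' Mean of the last three PSC peaks normalised to the first.
#'
#' @param psc_peaks numeric vector of at least four peak amplitudes
#' @return a single number
#' @export
facilitation_index <- function(psc_peaks) {
  stopifnot(length(psc_peaks) >= 4, psc_peaks[1] > 0)
  mean(tail(psc_peaks, 3)) / psc_peaks[1]
}

#' Probe-averaged facilitation indices
#'
#' Runs [facilitation_protocol()] for each frequency at several probe
#' cells spread along the lamella (each with its own stimulation pool,
#' emulating the experimental sample of recorded cells) and averages the
#' indices per frequency.
#'
#' @param network a `dg_network`
#' @param freqs stimulation frequencies (Hz)
#' @param probe_positions probe positions along the lamella (micrometres)
#' @param ... passed to [facilitation_protocol()]
#' @return data frame `freq`, `index` (mean), `sd`, `n`
#' @export
facilitation_curve <- function(network, freqs = c(1, 10, 30, 50),
                               probe_positions = c(600, 800, 1000, 1200,
                                                   1400),
                               ...) {
  gc_pos <- network$positions$gc
  rows <- lapply(freqs, function(fr) {
    idx <- vapply(probe_positions, function(pp) {
      pb <- which.min(abs(gc_pos - pp))
      tryCatch(facilitation_protocol(network, fr, probe = pb,
                                     ...)$facilitation_index,
               error = function(e) NA_real_)
    }, numeric(1))
    # indices outside triple SD (typically a probe with a very small
    # initial IPSC) are removed before averaging
    ok <- !is.na(idx)
    if (sum(ok) >= 3) {
      z <- abs(idx - mean(idx[ok], na.rm = TRUE))
      ok <- ok & z <= 3 * sd(idx[ok], na.rm = TRUE)
    }
    data.frame(freq = fr, index = mean(idx[ok]),
               sd = sd(idx[ok]), n = sum(ok))
  })
  do.call(rbind, rows)
}


# Trial-averaged compound IPSC of one synchronous (staggered) volley.
volley_peak <- function(network, probe, n_pool, pulse_ms = 2,
                        amplitude = 5000, stagger_ms = 4, n_trials = 3) {
  gc_pos <- network$positions$gc
  pool <- setdiff(order(abs(gc_pos - gc_pos[probe])),
                  probe)[seq_len(n_pool)]
  inj <- data.frame(cell = pool,
                    start = 20 + seq(0, stagger_ms,
                                     length.out = n_pool),
                    duration = pulse_ms, amplitude = amplitude)
  # a pool counts as reliable only if its weakest trial still responds
  min(vapply(seq_len(n_trials), function(tr) {
    res <- run_simulation(network, duration = 100, injections = inj,
                          probes = probe,
                          noise_seed = derive_seed(network$seed_network,
                                                   "network") + 557L * tr)
    max(res$probe_ipsc[, 1])
  }, numeric(1)))
}

# Smallest stimulated pool whose single-volley IPSC reaches
# `target_first` of the probe's single-volley saturation (minimal
# stimulation power, calibrated per probe as in the slice experiments).
calibrate_pool <- function(network, probe, target_first = 0.25,
                           ...) {
  n_gc <- network$counts[["gc"]]
  sat <- volley_peak(network, probe, round(0.08 * n_gc), ...)
  target <- target_first * sat
  lo <- max(1L, round(0.008 * n_gc))
  hi <- round(0.06 * n_gc)
  if (volley_peak(network, probe, lo, ...) >= target) return(lo)
  while (hi - lo > max(1L, round(0.0025 * n_gc))) {
    mid <- round((lo + hi) / 2)
    if (volley_peak(network, probe, mid, ...) >= target) hi <- mid
    else lo <- mid
  }
  hi
}


# Effective decay time constant of the compound IPSC immediately before
# a pulse (log-linear fit to the preceding 6 ms); extrapolating from the
# local slope stays accurate even when the compound decay is a mixture
# of components.
local_decay_tau <- function(trace, time, onset, span = 6) {
  i1 <- findInterval(onset, time)
  i0 <- findInterval(max(onset - span, 0), time)
  seg <- trace[i0:i1]
  if (length(seg) < 10 || any(seg <= 0) || seg[1] <= seg[length(seg)])
    return(Inf)   # no decaying baseline to extrapolate
  tt <- time[i0:i1]
  fit <- stats::lm(log(seg) ~ tt)
  tau <- -1 / coef(fit)[2]
  if (!is.finite(tau) || tau <= 1 || tau > 200) Inf else tau
}
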