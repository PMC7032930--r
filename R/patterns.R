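#' Input pattern configuration
#'
#' Parameters of the perforant-path input pattern family: `n_patterns`
#' patterns of `pattern_size` adjacent afferents stepped by `increment`
#' (pattern `p` activates afferents `(p-1)*increment + 1 ...
#' (p-1)*increment + pattern_size`), each carrying a sinusoid-modulated
#' inhomogeneous Poisson train. A shared afferent carries the identical
#' train in every pattern that contains it, so pairwise input overlap is
#' controlled purely by the afferent sets.
#'
#' @param n_afferents number of PP afferents (400)
#' @param pattern_size active afferents per pattern (24)
#' @param n_patterns number of patterns (25)
#' @param increment afferent shift between consecutive patterns (1)
#' @param mod_freq modulation frequency, Hz (10 theta / 30 slow gamma)
#' @param peak_rate peak of the sinusoidal rate profile (Hz)
#' @param min_rate minimum of the rate profile (Hz)
#' @param duration train duration (ms)
#' @param seed_input base seed; afferent `a` uses `xor(seed_input, a)`
#' @return an object of class `dg_input_config`
#' @export
input_config <- function(n_afferents = 400, pattern_size = 24,
                         n_patterns = 25, increment = 1, mod_freq = 10,
                         peak_rate = 100, min_rate = 0, duration = 600,
                         seed_input = 1L) {
  if (pattern_size + (n_patterns - 1) * increment > n_afferents)
    stop("pattern family overflows the afferent index range")
  if (peak_rate < min_rate) stop("peak_rate must be >= min_rate")
  stopifnot(min_rate >= 0, duration > 0, mod_freq >= 0)
  structure(list(n_afferents = as.integer(n_afferents),
                 pattern_size = as.integer(pattern_size),
                 n_patterns = as.integer(n_patterns),
                 increment = as.integer(increment),
                 mod_freq = mod_freq, peak_rate = peak_rate,
                 min_rate = min_rate, duration = duration,
                 seed_input = as.integer(seed_input)),
            class = "dg_input_config")
}

#' Sinusoidal rate profile
#'
#' Rate function oscillating between `minimum` and `peak` at `mod_freq`,
#' starting at the minimum (trough) at `t = 0` unless `phase` is given
#' (radians added to the trough-start phase). The time average over whole
#' cycles is `(peak + minimum) / 2`.
#'
#' @param mod_freq modulation frequency (Hz)
#' @param peak peak rate (Hz)
#' @param minimum minimum rate (Hz)
#' @param phase phase offset (radians)
#' @return function of time (ms) returning the rate (Hz), with the peak
#'   rate attached as attribute `"peak"`
#' @export
rate_profile <- function(mod_freq, peak, minimum = 0, phase = 0) {
  if (peak < minimum) stop("peak rate below minimum rate")
  f <- function(t) {
    minimum + (peak - minimum) *
      (1 - cos(2 * pi * mod_freq * t / 1000 + phase)) / 2
  }
  attr(f, "peak") <- peak
  f
}

#' Inhomogeneous Poisson spike train
#'
#' Thinning (Lewis-Shedler) sampler: homogeneous Poisson candidates at the
#' maximal rate are retained with probability `rate(t) / rate_max`. Spike
#' counts in any window are Poisson with mean equal to the integrated
#' rate. Deterministic for a fixed seed.
#'
#' @param rate function of time (ms) returning Hz, or a single constant
#'   rate (Hz)
#' @param duration train duration (ms)
#' @param seed RNG seed
#' @param rate_max upper bound of the rate; defaults to the `"peak"`
#'   attribute of `rate`, or to a grid maximum
#' @return sorted spike times (ms)
#' @export
inhomogeneous_poisson <- function(rate, duration, seed, rate_max = NULL) {
  if (is.numeric(rate) && length(rate) == 1) {
    r0 <- rate
    rate <- function(t) rep(r0, length(t))
    rate_max <- r0
  }
  if (is.null(rate_max)) {
    rate_max <- attr(rate, "peak")
    if (is.null(rate_max))
      rate_max <- max(rate(seq(0, duration, by = 0.1)))
  }
  probe <- rate(seq(0, duration, length.out = 101))
  if (any(probe < 0)) stop("negative rate")
  if (rate_max <= 0) return(numeric(0))
  with_seed(seed, {
    n <- rpois(1, rate_max * duration / 1000)
    tt <- sort(runif(n, 0, duration))
    keep <- runif(n) < rate(tt) / rate_max
    tt[keep]
  })
}

#' Generate a perforant-path pattern family
#'
#' Draws one spike train per afferent (from the per-afferent seed
#' `xor(seed_input, afferent)`) and assembles the `n_patterns` overlapping
#' patterns. Afferent trains are generated once and shared, so two
#' patterns agree bit-identically on their common afferents; the overlap
#' between patterns `p` and `q` is
#' `max(0, pattern_size - |p - q| * increment)` afferents.
#'
#' @param cfg an [input_config()]
#' @return object of class `dg_pattern_family`: `trains` (per-afferent
#'   list), `afferents` (per-pattern index sets), and `cfg`
#' @export
generate_pattern_family <- function(cfg) {
  stopifnot(inherits(cfg, "dg_input_config"))
  prof <- rate_profile(cfg$mod_freq, cfg$peak_rate, cfg$min_rate)
  used <- seq_len(cfg$pattern_size + (cfg$n_patterns - 1) * cfg$increment)
  trains <- vector("list", cfg$n_afferents)
  for (a in used) {
    trains[[a]] <- inhomogeneous_poisson(
      prof, cfg$duration, seed = bitwXor(cfg$seed_input, a))
  }
  afferents <- lapply(seq_len(cfg$n_patterns) - 1L, function(p) {
    p * cfg$increment + seq_len(cfg$pattern_size)
  })
  structure(list(trains = trains, afferents = afferents, cfg = cfg),
            class = "dg_pattern_family")
}

#' @export
print.dg_pattern_family <- function(x, ...) {
  cat(sprintf("PP pattern family: %d patterns x %d afferents of %d, %g Hz modulation, %g ms\n",
              x$cfg$n_patterns, x$cfg$pattern_size, x$cfg$n_afferents,
              x$cfg$mod_freq, x$cfg$duration))
  invisible(x)
}

#' Drive list for one pattern
#'
#' Expands pattern `p` of a family into the per-afferent drive list
#' expected by [run_simulation()] (silent afferents get empty trains).
#'
#' @param family a `dg_pattern_family`
#' @param p pattern index (1-based)
#' @return list of `n_afferents` spike-time vectors
#' @export
pattern_drive <- function(family, p) {
  stopifnot(p >= 1, p <= family$cfg$n_patterns)
  drive <- rep(list(numeric(0)), family$cfg$n_afferents)
  for (a in family$afferents[[p]]) drive[[a]] <- family$trains[[a]]
  drive
}

#' Input population rate vectors of a family
#'
#' Mean firing rate (Hz) of every afferent in every pattern within a time
#' window; the input side of the similarity analysis.
#'
#' @param family a `dg_pattern_family`
#' @param window `c(start, end)` ms
#' @return matrix `n_afferents x n_patterns`
#' @export
family_rate_matrix <- function(family,
                               window = c(0, family$cfg$duration)) {
  len_s <- (window[2] - window[1]) / 1000
  stopifnot(len_s > 0)
  counts <- vapply(family$trains, function(tr) {
    if (is.null(tr)) 0L else sum(tr >= window[1] & tr < window[2])
  }, integer(1))
  m <- matrix(0, family$cfg$n_afferents, family$cfg$n_patterns)
  for (p in seq_len(family$cfg$n_patterns)) {
    act <- family$afferents[[p]]
    m[act, p] <- counts[act] / len_s
  }
  m
}
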