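#' Population rate vector
#'
#' Mean firing rate (Hz) of every cell of a population within a time
#' window: spike count in the window divided by the window length.
#'
#' @param result a `dg_sim_result`
#' @param population `"gc"`, `"bc"`, `"hc"` or `"mc"`
#' @param window `c(start, end)` ms, within the simulation
#' @return numeric vector of length = population size
#' @export
rate_vector <- function(result, population = "gc",
                        window = c(0, result$duration)) {
  stopifnot(inherits(result, "dg_sim_result"))
  len_s <- (window[2] - window[1]) / 1000
  if (len_s <= 0) stop("empty window")
  if (!is.na(result$duration) && window[2] > result$duration + 1e-9)
    stop("window extends beyond the simulation")
  sp <- result$spikes
  sel <- sp$population == population & sp$time >= window[1] &
    sp$time < window[2]
  tabulate(sp$cell[sel], nbins = result$counts[[population]]) / len_s
}

#' Similarity of two population rate vectors
#'
#' Three measures: `"pearson"` (product-moment correlation), `"ndp"`
#' (normalised dot product / cosine similarity) and `"overlap"` (number of
#' coactive cells over number of cells active in either vector). Pearson
#' on a zero-variance vector and NDP on a zero-norm vector are undefined
#' and returned as `NA` (flagged missing; such pairs are excluded
#' downstream). Overlap of two all-silent vectors is likewise `NA`.
#'
#' @param a,b equal-length rate vectors
#' @param measure similarity measure
#' @return a single number (`NA` if undefined)
#' @export
similarity <- function(a, b, measure = c("pearson", "ndp", "overlap")) {
  measure <- match.arg(measure)
  stopifnot(length(a) == length(b))
  if (measure == "pearson") {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  } else if (measure == "ndp") {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(a * b) / (na * nb)
  } else {
    tot <- sum(a > 0 | b > 0)
    if (tot == 0) return(NA_real_)
    sum(a > 0 & b > 0) / tot
  }
}

# similarity between all columns of a matrix; returns condensed data frame
pairwise_similarity <- function(m, measure, with_self) {
  P <- ncol(m)
  idx <- which(upper.tri(matrix(0, P, P), diag = with_self), arr.ind = TRUE)
  r <- vapply(seq_len(nrow(idx)), function(k) {
    similarity(m[, idx[k, 1]], m[, idx[k, 2]], measure)
  }, numeric(1))
  data.frame(p = idx[, 1], q = idx[, 2], r = r)
}

#' All pattern-pair similarities for one condition
#'
#' Builds the `(R_in, R_out)` table over all pattern pairs of a family
#' run: `R_in` on the perforant-path rate vectors, `R_out` on the granule
#' cell rate vectors, in a common time window. With `with_self = TRUE`
#' self-comparisons are included (25 patterns give 325 pairs, otherwise
#' 300).
#'
#' @param results list of `dg_sim_result`, one per pattern, all from the
#'   same network and condition
#' @param family the `dg_pattern_family` that produced the drive
#' @param measure similarity measure, see [similarity()]
#' @param window `c(start, end)` ms
#' @param with_self include self-pairs
#' @return data frame `p, q, r_in, r_out` of class `dg_pairs` with the
#'   condition attached as an attribute
#' @export
all_pairs <- function(results, family,
                      measure = c("pearson", "ndp", "overlap"),
                      window = NULL, with_self = TRUE) {
  measure <- match.arg(measure)
  stopifnot(length(results) == family$cfg$n_patterns)
  conds <- unique(vapply(results, `[[`, "", "condition"))
  if (length(conds) != 1)
    stop("results mix conditions: ", paste(conds, collapse = ", "))
  if (is.null(window)) window <- c(0, results[[1]]$duration)
  m_in <- family_rate_matrix(family, window)
  m_out <- vapply(results, rate_vector, numeric(results[[1]]$counts[["gc"]]),
                  population = "gc", window = window)
  pin <- pairwise_similarity(m_in, measure, with_self)
  pout <- pairwise_similarity(m_out, measure, with_self)
  out <- data.frame(p = pin$p, q = pin$q, r_in = pin$r, r_out = pout$r)
  attr(out, "condition") <- conds
  attr(out, "measure") <- measure
  attr(out, "window") <- window
  class(out) <- c("dg_pairs", "data.frame")
  out
}

# bin index for R_in bins of width 0.1 on [0,1]; r == 1 goes to the top
# bin, values outside [0,1] return NA
rin_bin <- function(r) {
  b <- findInterval(r, seq(0, 1, by = 0.1), rightmost.closed = TRUE)
  b[r < 0 | r > 1] <- NA_integer_
  b
}

#' Binwise mean curve
#'
#' Mean `R_in` and mean `R_out` (or `delta`) within left-closed
#' right-open `R_in` bins of width 0.1 covering `[0, 1]` (`R_in = 1` falls
#' in the top bin). Pairs with undefined similarity and pairs outside
#' `[0, 1]` are excluded; empty bins are reported as `NA`.
#'
#' @param pairs data frame with `r_in` and a response column
#' @param response name of the response column (`"r_out"` or `"delta"`)
#' @return data frame `bin, lo, hi, n, mean_r_in, mean_response` of class
#'   `dg_curve`
#' @export
binwise_curve <- function(pairs, response = "r_out") {
  stopifnot(nrow(pairs) > 0, response %in% names(pairs))
  ok <- !is.na(pairs$r_in) & !is.na(pairs[[response]])
  b <- rin_bin(pairs$r_in[ok])
  keep <- !is.na(b)
  b <- b[keep]
  rin <- pairs$r_in[ok][keep]
  resp <- pairs[[response]][ok][keep]
  out <- data.frame(bin = 1:10, lo = seq(0, 0.9, by = 0.1),
                    hi = seq(0.1, 1, by = 0.1),
                    n = as.integer(tabulate(b, nbins = 10)),
                    mean_r_in = NA_real_, mean_response = NA_real_,
                    sd_response = NA_real_)
  for (k in unique(b)) {
    out$mean_r_in[k] <- mean(rin[b == k])
    out$mean_response[k] <- mean(resp[b == k])
    out$sd_response[k] <- sd(resp[b == k])
  }
  class(out) <- c("dg_curve", "data.frame")
  out
}

#' Mean separation (area to the unity line)
#'
#' Mean over occupied `R_in` bins of the binwise
#' `mean R_in - mean R_out` difference. Positive values mean pattern
#' separation (outputs less similar than inputs).
#'
#' @param curve a `dg_curve` from [binwise_curve()] with `r_out` response
#' @return a single number
#' @export
mean_delta_rout_full <- function(curve) {
  occ <- !is.na(curve$mean_response)
  if (!any(occ)) stop("all R_in bins are empty")
  mean(curve$mean_r_in[occ] - curve$mean_response[occ])
}

#' Isolated effect of a manipulation
#'
#' Pairwise difference in `R_out` between two conditions run on the same
#' input pattern combinations: for each pattern pair,
#' `delta = r_out(B) - r_out(A)`. Calling it as
#' `isolated_effect(full, no_fb)` therefore gives the isolated feedback
#' inhibition effect (how much higher the output correlation is without
#' the mossy-fiber drive of the feedback circuit). Averaging and
#' subtracting commute, so the binwise mean of `delta` equals the
#' difference of the binwise `r_out` means.
#'
#' @param pairs_a,pairs_b `dg_pairs` tables matched one-to-one by
#'   `(p, q)`
#' @return data frame `p, q, r_in, delta` of class `dg_pairs_delta`; the
#'   binwise curve is available through [binwise_curve()] with
#'   `response = "delta"` and the area through [mean_delta_isolated()]
#' @export
isolated_effect <- function(pairs_a, pairs_b) {
  key_a <- paste(pairs_a$p, pairs_a$q)
  key_b <- paste(pairs_b$p, pairs_b$q)
  if (!identical(sort(key_a), sort(key_b))) {
    miss <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("pair sets do not match; unmatched keys: ",
         paste(head(miss, 5), collapse = ", "))
  }
  m <- match(key_a, key_b)
  out <- data.frame(p = pairs_a$p, q = pairs_a$q, r_in = pairs_a$r_in,
                    delta = pairs_b$r_out[m] - pairs_a$r_out)
  class(out) <- c("dg_pairs_delta", "data.frame")
  out
}

#' @rdname isolated_effect
#' @param pairs_delta a `dg_pairs_delta`
#' @export
mean_delta_isolated <- function(pairs_delta) {
  curve <- binwise_curve(pairs_delta, response = "delta")
  occ <- !is.na(curve$mean_response)
  if (!any(occ)) stop("all R_in bins are empty")
  mean(curve$mean_response[occ])
}

#' Mean response in an input-similarity band
#'
#' Mean of the response column over pairs with `lo <= r_in <= hi`; the
#' headline statistic for highly similar inputs uses the band
#' `[0.9, 1]`.
#'
#' @param pairs a pairs table
#' @param response response column name
#' @param lo,hi band limits (inclusive)
#' @return a single number (`NA` when the band is empty)
#' @export
band_mean <- function(pairs, response = "delta", lo = 0.9, hi = 1) {
  sel <- !is.na(pairs$r_in) & pairs$r_in >= lo & pairs$r_in <= hi &
    !is.na(pairs[[response]])
  if (!any(sel)) return(NA_real_)
  mean(pairs[[response]][sel])
}

#' Coefficient of variation of the isolated effect
#'
#' Per-bin SD of `delta` divided by the bin mean, averaged over bins; only
#' bins fully inside `0.2 < R_in < 0.8` are included (at the borders very
#' small means make the ratio unreliable). Bins with a mean of exactly
#' zero are excluded with a warning.
#'
#' @param pairs_delta a `dg_pairs_delta`
#' @return a single number
#' @export
cov_delta <- function(pairs_delta) {
  curve <- binwise_curve(pairs_delta, response = "delta")
  sel <- curve$lo >= 0.2 & curve$hi <= 0.8 & !is.na(curve$mean_response)
  if (!any(sel)) stop("no occupied R_in bins inside (0.2, 0.8)")
  zero <- sel & curve$mean_response == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " bin(s) with zero mean")
    sel <- sel & !zero
  }
  mean(curve$sd_response[sel] / curve$mean_response[sel])
}

#' Time-resolved separation analysis
#'
#' Runs the full pipeline (rate vectors, similarity, binwise curve, area)
#' in consecutive windows of `window_len` ms. A trailing partial window
#' is dropped with a warning.
#'
#' @param results list of per-pattern `dg_sim_result`
#' @param family the generating `dg_pattern_family`
#' @param window_len window length (ms), e.g. 100 or 33
#' @param measure similarity measure
#' @param with_self include self-pairs
#' @return list with one element per window: `window`, `pairs`, `curve`,
#'   `mean_delta_rout`
#' @export
time_resolved <- function(results, family, window_len = 100,
                          measure = "pearson", with_self = TRUE) {
  duration <- results[[1]]$duration
  if (window_len > duration) stop("window_len exceeds the simulation")
  n_win <- floor(duration / window_len)
  if (n_win * window_len < duration - 1e-9)
    warning("dropping a partial trailing window")
  lapply(seq_len(n_win), function(k) {
    win <- c((k - 1) * window_len, k * window_len)
    pairs <- all_pairs(results, family, measure = measure, window = win,
                       with_self = with_self)
    curve <- binwise_curve(pairs)
    list(window = win, pairs = pairs, curve = curve,
         mean_delta_rout = mean_delta_rout_full(curve))
  })
}

#' Activity metrics of one run
#'
#' Fraction of granule cells with at least one spike in the window, the
#' mean rate among those active cells, and the mean population rates of
#' the interneuron populations.
#'
#' @param result a `dg_sim_result`
#' @param window `c(start, end)` ms
#' @return list `active_fraction` (percent), `mean_rate_active` (Hz),
#'   `interneuron_rates` (named, Hz)
#' @export
activity_metrics <- function(result, window = c(0, result$duration)) {
  rv <- rate_vector(result, "gc", window)
  act <- rv > 0
  list(active_fraction = 100 * mean(act),
       mean_rate_active = if (any(act)) mean(rv[act]) else 0,
       interneuron_rates = c(
         bc = mean(rate_vector(result, "bc", window)),
         hc = mean(rate_vector(result, "hc", window)),
         mc = mean(rate_vector(result, "mc", window))))
}
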