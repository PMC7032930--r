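#' Surrogate specification
#'
#' Parameters of the surrogate rate-vector generator that emulates the
#' statistical structure of granule-cell population rate vectors: sparse
#' activity (a fraction of cells active) with log-normal rates among
#' active cells, and a controlled expected Pearson correlation between
#' paired vectors.
#'
#' @param n_cells population size
#' @param active_fraction percent of cells active, in (0, 100]
#' @param target_r desired expected Pearson correlation in [0, 1]
#' @param mu,sigma log-normal parameters of the active-cell rates
#' @param seed RNG seed
#' @return object of class `dg_surrogate_spec`
#' @export
surrogate_spec <- function(n_cells, active_fraction = 5, target_r = 0.5,
                           mu = 1, sigma = 0.5, seed = 1L) {
  if (active_fraction <= 0 || active_fraction > 100)
    stop("active_fraction must be in (0, 100]")
  if (target_r < 0 || target_r > 1)
    stop("target_r must be in [0, 1]")
  stopifnot(n_cells >= 2, sigma >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 active_fraction = active_fraction, target_r = target_r,
                 mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "dg_surrogate_spec")
}

#' Correlated surrogate rate vectors
#'
#' Shared-component mixture: a fraction `target_r` of cells carry the
#' identical (shared) value in both vectors, the rest are independent
#' draws from the same sparse log-normal marginal. Because shared entries
#' contribute the full marginal variance to the covariance, the expected
#' Pearson correlation equals the shared fraction, i.e. `target_r`
#' exactly; sparsity equals `active_fraction` in expectation in both
#' vectors.
#'
#' @param spec a [surrogate_spec()]
#' @return list `a`, `b` (rate vectors, Hz) and `shared` (logical mask)
#' @export
correlated_rate_vectors <- function(spec) {
  stopifnot(inherits(spec, "dg_surrogate_spec"))
  n <- spec$n_cells
  f <- spec$active_fraction / 100
  draw <- function(k) {
    v <- numeric(k)
    on <- runif(k) < f
    v[on] <- rlnorm(sum(on), spec$mu, spec$sigma)
    v
  }
  with_seed(spec$seed, {
    n_sh <- round(spec$target_r * n)
    shared <- c(rep(TRUE, n_sh), rep(FALSE, n - n_sh))
    s <- draw(n_sh)
    a <- b <- numeric(n)
    a[shared] <- s
    b[shared] <- s
    a[!shared] <- draw(n - n_sh)
    b[!shared] <- draw(n - n_sh)
    list(a = a, b = b, shared = shared)
  })
}

#' Poisson raster from a rate vector
#'
#' Homogeneous Poisson spike trains per cell, shaped like a simulator
#' result so surrogate data are drop-in for the analysis layer;
#' [rate_vector()] recovers the input rates within sampling error.
#'
#' @param rates per-cell rates (Hz)
#' @param duration raster duration (ms)
#' @param seed RNG seed
#' @param population population label of the raster
#' @return a `dg_sim_result` (spikes and counts only)
#' @export
raster_from_rates <- function(rates, duration, seed, population = "gc") {
  stopifnot(all(rates >= 0))
  with_seed(seed, {
    counts <- rpois(length(rates), rates * duration / 1000)
    cells <- rep(seq_along(rates), counts)
    times <- runif(sum(counts), 0, duration)
  })
  ord <- order(times)
  pop_counts <- c(pp = 0L, gc = 0L, bc = 0L, hc = 0L, mc = 0L)
  pop_counts[population] <- length(rates)
  structure(list(
    spikes = data.frame(population = rep(population, sum(counts)),
                        cell = cells[ord], time = times[ord]),
    probe_ipsc = NULL, probe_epsc = NULL, probes = NULL, time = NULL,
    counts = pop_counts, condition = "SURROGATE", duration = duration,
    dt = NA_real_, seed_network = NA_integer_),
    class = "dg_sim_result")
}
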