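# Independent oracles used across the suite. These re-derive expected
# values by brute force and must stay independent of the package's own
# implementation paths.

# Brute-force time-stepped integration of the facilitating synapse: the
# utilisation u relaxes with tau_facil on a fine time grid and jumps by
# U*(1-u) at each spike; increments are weight * u / U. Also returns the
# conductance trace by explicit Euler decay.
tm_oracle <- function(spike_times, weight, tau_decay, tau_facil, U,
                      dt = 0.001, t_max = max(spike_times) + 5 * tau_decay) {
  n_steps <- ceiling(t_max / dt)
  u <- 0
  g <- 0
  inc <- numeric(length(spike_times))
  peaks <- numeric(length(spike_times))
  next_spike <- 1
  g_trace_max <- 0
  for (s in seq_len(n_steps)) {
    t <- s * dt
    if (tau_facil > 0) u <- u - dt * u / tau_facil
    g <- g - dt * g / tau_decay
    while (next_spike <= length(spike_times) &&
           spike_times[next_spike] <= t) {
      if (tau_facil > 0) {
        u <- u + U * (1 - u)
        inc[next_spike] <- weight * u / U
      } else {
        inc[next_spike] <- weight
      }
      g <- g + inc[next_spike]
      peaks[next_spike] <- g
      next_spike <- next_spike + 1
    }
    g_trace_max <- max(g_trace_max, g)
  }
  list(increments = inc, peaks = peaks, g_max = g_trace_max)
}

# Hand similarity measures on plain vectors.
oracle_pearson <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}
oracle_ndp <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
oracle_overlap <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# Brute-force group-by for the binwise curve.
oracle_binwise <- function(r_in, y) {
  bins <- pmin(floor(r_in * 10) + 1, 10)
  out <- data.frame(bin = 1:10, mean_r_in = NA_real_, mean_y = NA_real_)
  for (k in unique(bins)) {
    out$mean_r_in[k] <- mean(r_in[bins == k])
    out$mean_y[k] <- mean(y[bins == k])
  }
  out
}

# Small tuned network shared by simulation-level tests (cached per
# session; scale 0.25 keeps the suite fast).
small_net <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) {
      cfg <- network_config(scale = 0.25, keep_input = TRUE)
      cache <<- build_network(cfg, seed = seed)
    }
    cache
  }
})

small_family <- local({
  cache <- NULL
  function(mod_freq = 10, seed = 21) {
    key <- paste(mod_freq, seed)
    if (is.null(cache[[key]])) {
      cfg <- input_config(mod_freq = mod_freq, seed_input = seed)
      if (is.null(cache)) cache <<- list()
      cache[[key]] <<- generate_pattern_family(cfg)
    }
    cache[[key]]
  }
})


full_net <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache)) cache <<- build_network(network_config(), seed = seed)
    cache
  }
})
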