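# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration instead of the counting
# recursion, exhaustive window scans instead of the selection DP.

# Null distribution of U by complete enumeration of rank arrangements.
bf_mw_null_counts <- function(n1, n2) {
  n <- n1 + n2
  combs <- utils::combn(n, n1)
  u <- colSums(combs) - n1 * (n1 + 1) / 2
  tabulate(u + 1L, nbins = n1 * n2 + 1L)
}

# Exact two-sided p for observed samples, by enumerating every assignment
# of the pooled values to the two groups (doubled tail incl. point mass).
bf_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs_1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_obs <- min(u_obs_1, n1 * n2 - u_obs_1)
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) {
    u1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  })
  # doubled one-sided tails of the min-orientation statistic's parent U
  u1_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u1_all <= u_obs)
  hi <- mean(u1_all >= n1 * n2 - u_obs)
  min(1, lo + hi)
}

# Exhaustive search for the pair of non-overlapping windows of length `len`
# minimizing total event-sample overlap; ties resolved toward the earliest
# (first, then second) start. Returns the two 1-based start indices.
bf_best_two_windows <- function(ev_mask, len) {
  n <- length(ev_mask)
  cs <- cumsum(c(0, ev_mask))
  starts <- seq_len(n - len + 1L)
  cost <- cs[starts + len] - cs[starts]
  best <- NULL
  best_cost <- Inf
  for (i in starts) {
    j_min <- i + len
    if (j_min > max(starts)) break
    for (j in j_min:max(starts)) {
      tot <- cost[i] + cost[j]
      if (tot < best_cost) {
        best_cost <- tot
        best <- c(i, j)
      }
    }
  }
  best
}

# Simulate one contaminated 5-s segment and return the constrained-fit and
# naive-mean holding-current estimates (shared by robustness checks).
fit_vs_mean_once <- function(seed, event_rate_hz, i_hold = -50,
                             noise_sd = 3, duration_s = 5) {
  cfg <- sim_config(duration_s = duration_s, i_hold_pa = i_hold,
                    noise_sd_pa = noise_sd, event_rate_hz = event_rate_hz,
                    seed = seed)
  sim <- simulate_trace(cfg)
  h <- all_point_histogram(sim$trace)
  fit <- fit_gaussian_constrained(h)
  c(mu_fit = fit$mu_pa, naive = mean(sim$trace$samples))
}
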