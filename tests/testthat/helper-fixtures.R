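# Shared fixtures: datasets are generated once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete dataset exercising every planted feature.
tiny_dataset <- function() {
  cached("tiny", simulate_cohort(sim_config(
    n_sibships = 80, n_probes = 150, n_multimodal_probes = 6,
    n_bad_samples = 4, n_xy_probes = 12, n_crossreactive = 10,
    n_snp_overlap = 6, seed = 101
  )))
}

# A null cohort: no planted effects, no confounder coupling, no chip effects.
null_config <- function(n_sibships = 150, n_probes = 200, seed = 202,
                        chip_effect_sd = 0, ...) {
  sim_config(
    n_sibships = n_sibships, n_probes = n_probes,
    n_multimodal_probes = 0, n_bad_samples = 0, n_xy_probes = 0,
    n_crossreactive = 0, n_snp_overlap = 0, chip_effect_sd = chip_effect_sd,
    planted_effects = data.frame(probe = integer(), coefficient = numeric()),
    seed = seed, ...
  )
}

# Independent step-up implementation used as the BH oracle.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact hypergeometric upper tail by enumerating all draws (population <= 20).
hyper_enumeration_oracle <- function(k, m, n_bg, n_draw) {
  draws <- utils::combn(n_bg, n_draw)
  hits <- colSums(draws <= m)  # first m population members are "successes"
  mean(hits >= k)
}
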