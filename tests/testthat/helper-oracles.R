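# Independent oracles used across tests. These deliberately avoid the
# package's vectorized code paths.

# Brute-force argmax of f on [lo, hi] over a dense grid (default step 1e-6).
brute_argmax <- function(f, lo = 0, hi = 1, n = 1e6 + 1) {
  grid <- seq(lo, hi, length.out = n)
  grid[which.max(f(grid))]
}

# Scalar re-implementation of lifetime reproductive success at p = 0
# (no floods): sum clutch output over attempts, round half up, one
# individual at a time.
scalar_lrs_no_flood <- function(z, n, c) {
  total <- 0
  for (k in seq_len(n)) {
    total <- total + c * (1 - z)
  }
  floor(total + 0.5)
}

# Small helper: a fitness pair made of two constant functions.
constant_pair <- function(vm, ve) {
  fitness_pair(function(z) rep(vm, length(z)),
               function(z) rep(ve, length(z)))
}

# Compact simulation config for fast tests.
small_config <- function(N0 = 200L, K = 200L, generations = 50L, seed = 1L,
                         p = 0.1, s = 1, h = 0.4, n = 1L, c = 5,
                         m = 0.001, m_size = 0.05, ...) {
  sim_config(N0 = N0, K = K, m = m, m_size = m_size,
             generations = generations, seed = seed,
             regime = environment_regime(p = p, s = s, h = h),
             life_history = life_history(n = n, c = c, ...))
}
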