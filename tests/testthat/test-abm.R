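test_that("single-attempt nesting success follows the flood/predation rule", {
  expect_equal(nest_fitness(0.5, 0.4), 0.5)   # above water: predation only
  expect_equal(nest_fitness(0.3, 0.4), 0)     # below water: destroyed
  expect_equal(nest_fitness(0.3, 0), 0.7)     # no flood
  expect_equal(nest_fitness(c(0, 1, 0.4), 0.4), c(0, 0, 0.6))
  expect_error(nest_fitness(1.2, 0), "\\[0, 1\\]")
  expect_error(nest_fitness(0.5, -0.1), ">= 0")
})

test_that("flood schedules respect p and keep height constant at 0.4", {
  reg <- environment_regime(p = 0, s = 1, h = 0.4)
  set.seed(1)
  sched <- draw_flood_schedule(reg, 5)
  expect_false(any(sched$flooded))
  reg1 <- environment_regime(p = 1, s = 1, h = 0.4)
  sched1 <- draw_flood_schedule(reg1, 3)
  expect_true(all(sched1$flooded))
  expect_equal(sched1$height, rep(0.4, 3))
  # Monte-Carlo: flooded fraction matches the binomial law at p = 0.15
  reg15 <- environment_regime(p = 0.15)
  set.seed(42)
  frac <- mean(vapply(1:10000, function(i) draw_flood_schedule(reg15, 1)$flooded,
                      logical(1)))
  expect_lt(abs(frac - 0.15), 4 * sqrt(0.15 * 0.85 / 10000))
})

test_that("variable flood heights stay within [0, 1] and center on h", {
  reg <- environment_regime(p = 1, s = 1, h = 0.4, flood_height_noise = 0.2)
  set.seed(7)
  hts <- replicate(2000, draw_flood_schedule(reg, 1)$height)
  expect_true(all(hts >= 0 & hts <= 1))
  expect_lt(abs(mean(hts) - 0.4), 0.02)
  expect_gt(sd(hts), 0.1)
})

test_that("lifetime reproductive success sums attempts and rounds half up", {
  no_flood <- structure(list(flooded = c(FALSE, FALSE), height = c(0, 0)),
                        class = "flood_schedule")
  expect_equal(lifetime_reproductive_success(0.2, no_flood, s = 1, c = 5), 8)
  flooded <- structure(list(flooded = TRUE, height = 0.4),
                       class = "flood_schedule")
  set.seed(1)
  expect_equal(lifetime_reproductive_success(0.2, flooded, s = 1, c = 5), 0)
  # half-up rule: 5 * 0.5 = 2.5 -> 3
  expect_equal(lifetime_reproductive_success(0.5, flooded, s = 1, c = 5), 3)
  # scope 0: the flood never touches the nest
  expect_equal(lifetime_reproductive_success(0.2, flooded, s = 0, c = 5), 4)
})

test_that("mutation is rare, small, and clamped to [0, 1]", {
  z <- runif(1000)
  expect_identical(mutate_offspring(z, m = 0, m_size = 0.05), z)
  set.seed(3)
  top <- mutate_offspring(rep(1, 1000), m = 1, m_size = 0.5)
  expect_true(all(top >= 0 & top <= 1))
  expect_true(any(top == 1))  # positive deviates clamp back to 1
  # deviate SD matches m.size when far from the boundaries
  set.seed(4)
  dev <- mutate_offspring(rep(0.5, 1e5), m = 1, m_size = 0.05) - 0.5
  expect_lt(abs(sd(dev) - 0.05), 0.002)
  expect_lt(abs(mean(dev)), 0.002)
})

test_that("recruitment caps at K by uniform removal", {
  off <- runif(4000)
  expect_identical(recruit(off, 5000), off)
  set.seed(5)
  big <- runif(6000)
  kept <- recruit(big, 5000)
  expect_length(kept, 5000)
  expect_true(all(kept %in% big))
  # inclusion probability ~ 5/6 for a marked offspring
  marked <- big[1]
  hits <- mean(replicate(600, marked %in% recruit(big, 5000)))
  expect_lt(abs(hits - 5 / 6), 4 * sqrt((5 / 6) * (1 / 6) / 600))
  expect_length(recruit(numeric(0), 5000), 0)
})

test_that("one generation step matches the exact no-flood selection oracle", {
  # with p = 0, m = 0 and no capacity limit, each parent contributes exactly
  # round(n * c * (1 - z)) copies of its phenotype
  for (case in 1:5) {
    set.seed(100 + case)
    nz <- sample(10:100, 1)
    z <- round(runif(nz), 6)
    n <- sample(1:5, 1)
    cfg <- small_config(N0 = nz, K = 1000000L, p = 0, n = n, m = 0)
    st <- population_state(z)
    nxt <- step_generation(st, cfg)
    w_expected <- vapply(z, scalar_lrs_no_flood, numeric(1), n = n, c = 5)
    expect_identical(sort(nxt$phenotypes), sort(rep(z, w_expected)))
    expect_equal(nxt$generation, 1L)
  }
})

test_that("a flood above everyone's nest wipes the population out", {
  cfg <- small_config(p = 1, s = 1, h = 0.4, n = 1)
  st <- population_state(runif(100, 0, 0.39))
  nxt <- step_generation(st, cfg)
  expect_length(nxt$phenotypes, 0)
  # extinction is absorbing and stepping an empty population is idempotent
  again <- step_generation(nxt, cfg)
  expect_length(again$phenotypes, 0)
  expect_equal(again$generation, 2L)
})

test_that("stepping is deterministic given the RNG state", {
  cfg <- small_config(p = 0.5, s = 0.8, n = 3)
  st <- population_state(runif(200))
  set.seed(9)
  a <- step_generation(st, cfg)
  set.seed(9)
  b <- step_generation(st, cfg)
  expect_identical(a, b)
})

test_that("scope draws are per nest: affected fraction follows Binomial(N, s)", {
  # all z below h, one guaranteed flood, no mutation, no cap:
  # unaffected nests yield round(5 * 0.7) = 4 offspring, affected yield 0
  N <- 10000L
  cfg <- small_config(N0 = N, K = 100000000L, p = 1, s = 0.3, n = 1, m = 0)
  st <- population_state(rep(0.3, N))
  set.seed(11)
  nxt <- step_generation(st, cfg)
  unaffected <- length(nxt$phenotypes) / 4
  pt <- binom.test(N - unaffected, N, p = 0.3)$p.value
  expect_gt(pt, 0.001)
})

test_that("population invariants hold along a stochastic run", {
  cfg <- small_config(N0 = 300, K = 250, generations = 60, p = 0.2, s = 0.9,
                      n = 2, m = 0.05, m_size = 0.2)
  set.seed(21)
  st <- population_state(runif(cfg$N0))
  for (t in 1:60) {
    st <- step_generation(st, cfg)
    expect_lte(length(st$phenotypes), cfg$K)
    expect_true(all(st$phenotypes >= 0 & st$phenotypes <= 1))
    if (!length(st$phenotypes)) break
  }
  # heredity: with m = 0 no new phenotype values ever appear
  cfg0 <- small_config(N0 = 200, K = 200, p = 0.15, m = 0)
  set.seed(22)
  st <- population_state(runif(200))
  pool <- unique(st$phenotypes)
  for (t in 1:50) {
    st <- step_generation(st, cfg0)
    expect_true(all(st$phenotypes %in% pool))
  }
})

test_that("replicates are reproducible and trajectories truncate at extinction", {
  cfg <- small_config(N0 = 500, K = 500, generations = 100, p = 0.2, seed = 31)
  a <- run_replicate(cfg)
  b <- run_replicate(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$extinct, b$extinct)
  # generations = 0: trajectory is the initial state only
  cfg0 <- small_config(N0 = 5000, K = 5000, generations = 0, seed = 32)
  r0 <- run_replicate(cfg0)
  expect_equal(nrow(r0$trajectory), 1L)
  expect_lt(abs(r0$trajectory$mean_z - 0.5), 0.02)
  # forced extinction: last row records size 0 and the run stops there
  cfge <- sim_config(N0 = 100, K = 100, generations = 50, seed = 33,
                     regime = environment_regime(p = 1, s = 1, h = 1),
                     life_history = life_history(n = 1))
  re <- run_replicate(cfge)
  expect_true(re$extinct)
  expect_equal(re$trajectory$pop_size[nrow(re$trajectory)], 0)
  expect_equal(nrow(re$trajectory), re$extinction_generation + 1L)
})

test_that("selection without floods drives nesting toward the ground", {
  # with n = 5 the fitness steps are fine enough to push the mean below 0.05;
  # with n = 1 rounding makes all z in [0, 0.1] selectively equivalent, so
  # the population is only confined to that band
  cfg5 <- sim_config(generations = 600, seed = 41,
                     regime = environment_regime(p = 0),
                     life_history = life_history(n = 5))
  r5 <- run_replicate(cfg5)
  expect_false(r5$extinct)
  expect_lt(r5$trajectory$mean_z[nrow(r5$trajectory)], 0.05)
  cfg1 <- sim_config(generations = 600, seed = 42,
                     regime = environment_regime(p = 0),
                     life_history = life_history(n = 1))
  r1 <- run_replicate(cfg1)
  expect_lt(r1$trajectory$mean_z[nrow(r1$trajectory)], 0.11)
})

test_that("overlapping generations keep adults alive and within capacity", {
  cfg <- sim_config(N0 = 300, K = 300, m = 0.001, m_size = 0.05,
                    generations = 30, seed = 51,
                    regime = environment_regime(p = 0.2),
                    life_history = life_history(n = 1, overlap = TRUE,
                                                adult_survival = 0.8))
  set.seed(51)
  st <- population_state(runif(300))
  for (t in 1:30) {
    st <- step_generation(st, cfg)
    expect_lte(length(st$phenotypes), cfg$K)
  }
  expect_gt(max(st$ages), 0)  # some adults survived at least one year
  # adult flood mortality: a full-scope flood kills low adults too
  cfgm <- sim_config(N0 = 100, K = 100, generations = 1, seed = 52,
                     regime = environment_regime(p = 1, s = 1, h = 0.4),
                     life_history = life_history(n = 1, overlap = TRUE,
                                                 adult_survival = 1,
                                                 adult_mortality = TRUE))
  st <- population_state(c(rep(0.2, 50), rep(0.6, 50)))
  set.seed(52)
  nxt <- step_generation(st, cfgm)
  expect_false(any(nxt$phenotypes[nxt$ages > 0] < 0.4))
})
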