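# Forward-time individual-based model of nest-height evolution under
# stochastic flooding.
#
# RNG draw order within one generation (fixed; reproducibility contract):
#   1. flood indicators, one uniform per breeding attempt
#   2. realized flood heights (only when flood_height_noise > 0)
#   3. per flooded attempt, in attempt order: one scope uniform per individual
#   4. overlap variant only: one adult-survival uniform per adult
#   5. recruitment subsample (only when offspring exceed capacity)
#   6. mutation: one uniform per recruit, then one normal deviate per mutant

# Round half away from zero for non-negative x ("to the nearest integer",
# half rounds up). base::round() rounds half to even and must not be used here.
round_half_up <- function(x) floor(x + 0.5)

#' Single-attempt nesting success
#'
#' Reproductive success of one nesting attempt: predation removes a fraction
#' of the clutch that increases linearly with nest height, and a flood
#' destroys the nest entirely if it sits below the water level, i.e.
#' \eqn{W(z; h) = 1 - z} for \eqn{z \ge h} and 0 otherwise. A water level of
#' 0 encodes "no flood at this nest".
#'
#' @param z Nest-height phenotype(s) in \eqn{[0, 1]}.
#' @param water_level Effective water level(s), >= 0.
#' @return Survival fraction(s) in \eqn{[0, 1]}.
#' @export
nest_fitness <- function(z, water_level) {
  if (any(z < 0 | z > 1)) {
    stop("`z` must lie in [0, 1]", call. = FALSE)
  }
  if (any(water_level < 0)) {
    stop("`water_level` must be >= 0", call. = FALSE)
  }
  (1 - z) * (z >= water_level)
}

# Realized flood heights for k events under a regime. Constant h by default;
# the time-varying variant draws from a normal centered on h, rejection-
# truncated to [0, 1].
.flood_heights <- function(regime, k) {
  if (regime$flood_height_noise <= 0) {
    return(rep.int(regime$h, k))
  }
  out <- stats::rnorm(k, regime$h, regime$flood_height_noise)
  bad <- which(out < 0 | out > 1)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), regime$h, regime$flood_height_noise)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

#' Draw the flood schedule for one breeding season
#'
#' Each of the `n` breeding attempts in a season is an independent
#' population-wide flood draw with probability `p`; this is what allows
#' multiple flooding events within a single season. Scope is applied per nest
#' later, when individual fitness is computed.
#'
#' @param regime An [environment_regime()].
#' @param n Number of breeding attempts.
#' @return A `flood_schedule`: list with logical `flooded` and numeric
#'   `height` (0 for attempts without a flood), both of length `n`.
#' @export
draw_flood_schedule <- function(regime, n) {
  n <- .check_count(n, "n", min = 1L)
  flooded <- stats::runif(n) < regime$p
  height <- numeric(n)
  if (any(flooded)) {
    height[flooded] <- .flood_heights(regime, sum(flooded))
  }
  structure(list(flooded = flooded, height = height), class = "flood_schedule")
}

#' Lifetime reproductive success of one individual
#'
#' Sums clutch output over the `n` attempts of a season,
#' \eqn{w_i = \left[\sum_k c \, W(z_i; h_{i,k})\right]}, rounded once to the
#' nearest integer (half up). In a flooded attempt the individual's nest is
#' affected with independent probability `s`; the effective water level is the
#' flood height if affected and 0 otherwise.
#'
#' @param z Phenotype of the individual.
#' @param schedule A [draw_flood_schedule()] result.
#' @param s Scope.
#' @param c Clutch constant.
#' @return Non-negative integer offspring count.
#' @export
lifetime_reproductive_success <- function(z, schedule, s, c) {
  .check_prob(s, "s")
  level <- numeric(length(schedule$flooded))
  for (k in which(schedule$flooded)) {
    if (stats::runif(1) < s) level[k] <- schedule$height[k]
  }
  round_half_up(sum(c * nest_fitness(z, level)))
}

#' Mutate offspring phenotypes
#'
#' Each offspring inherits its parent's phenotype exactly with probability
#' `1 - m`; with probability `m` a normal deviate (mean 0, SD `m_size`) is
#' added and the result is clamped to \eqn{[0, 1]} (nesting cannot occur
#' below ground or above the reeds).
#'
#' @param parent_z Parental phenotype vector.
#' @param m Per-offspring mutation probability.
#' @param m_size Mutational deviate standard deviation.
#' @return Phenotype vector of the same length.
#' @export
mutate_offspring <- function(parent_z, m, m_size) {
  out <- parent_z
  n <- length(out)
  if (n == 0L || m <= 0) {
    return(out)
  }
  mut <- stats::runif(n) < m
  k <- sum(mut)
  if (k) {
    out[mut] <- pmin(1, pmax(0, out[mut] + stats::rnorm(k, 0, m_size)))
  }
  out
}

#' Recruit offspring up to carrying capacity
#'
#' If more than `K` offspring are produced, a uniform random subset of exactly
#' `K` is kept (stochastic removal without replacement; no competitive
#' differences among offspring from different attempts).
#'
#' @param offspring Numeric vector of offspring phenotypes.
#' @param K Carrying capacity.
#' @return The recruited phenotype vector (length `<= K`).
#' @export
recruit <- function(offspring, K) {
  K <- .check_count(K, "K", min = 0L)
  if (length(offspring) <= K) {
    return(offspring)
  }
  offspring[sample.int(length(offspring), K)]
}

# One generation, vectorized over the whole population. Returns the successor
# phenotype/age vectors plus the realized flood heights of the season.
.step_core <- function(z, ages, config) {
  reg <- config$regime
  lh <- config$life_history
  N <- length(z)
  if (N == 0L) {
    return(list(z = numeric(0), ages = integer(0), floods = numeric(0)))
  }
  sched <- draw_flood_schedule(reg, lh$n)
  base <- 1 - z
  fit <- numeric(N)
  adult_ok <- TRUE
  for (k in seq_len(lh$n)) {
    if (sched$flooded[k]) {
      hk <- sched$height[k]
      affected <- stats::runif(N) < reg$s
      survived <- !affected | (z >= hk)
      fit <- fit + base * survived
      if (lh$adult_mortality) adult_ok <- adult_ok & survived
    } else {
      fit <- fit + base
    }
  }
  w <- round_half_up(lh$c * fit)
  offspring <- rep.int(z, w)
  if (lh$overlap) {
    alive <- adult_ok & (stats::runif(N) < lh$adult_survival)
    az <- z[alive]
    aa <- ages[alive] + 1L
    if (length(az) > config$K) {
      keep <- sample.int(length(az), config$K)
      az <- az[keep]
      aa <- aa[keep]
    }
    recruits <- recruit(offspring, config$K - length(az))
    recruits <- mutate_offspring(recruits, config$m, config$m_size)
    list(z = c(az, recruits),
         ages = c(aa, integer(length(recruits))),
         floods = sched$height[sched$flooded])
  } else {
    recruits <- recruit(offspring, config$K)
    recruits <- mutate_offspring(recruits, config$m, config$m_size)
    list(z = recruits, ages = integer(length(recruits)),
         floods = sched$height[sched$flooded])
  }
}

#' Advance a population by one generation
#'
#' Draws one flood schedule shared by the population, computes every
#' individual's integer lifetime reproductive success, recruits offspring up
#' to the carrying capacity, and mutates the recruits. Under the overlap
#' variant adults additionally survive with probability `adult_survival`
#' (dying first in floods if `adult_mortality` is set) and count against `K`.
#' Uses the current R RNG stream; an extinct population steps to an extinct
#' population.
#'
#' @param state A [population_state()].
#' @param config A [sim_config()].
#' @return The successor [population_state()].
#' @export
step_generation <- function(state, config) {
  res <- .step_core(state$phenotypes, state$ages, config)
  population_state(res$z, res$ages, state$generation + 1L)
}

# Core simulation loop over `generations` steps from an explicit starting
# population. Records per-generation summaries including the starting state.
.simulate <- function(z, ages, config, generations, start_generation = 0L,
                      record_floods = FALSE, progress = FALSE) {
  mean_z <- sd_z <- pop <- numeric(generations + 1L)
  nrec <- 1L
  mean_z[1L] <- if (length(z)) mean(z) else NA_real_
  sd_z[1L] <- if (length(z) > 1L) stats::sd(z) else NA_real_
  pop[1L] <- length(z)
  floods <- if (record_floods) vector("list", generations) else NULL
  extinct <- length(z) == 0L
  extinction_generation <- if (extinct) start_generation else NA_integer_
  if (!extinct) {
    for (t in seq_len(generations)) {
      res <- .step_core(z, ages, config)
      z <- res$z
      ages <- res$ages
      nrec <- nrec + 1L
      pop[nrec] <- length(z)
      mean_z[nrec] <- if (length(z)) mean(z) else NA_real_
      sd_z[nrec] <- if (length(z) > 1L) stats::sd(z) else NA_real_
      if (record_floods && length(res$floods)) {
        floods[[t]] <- tibble::tibble(generation = start_generation + t,
                                      height = res$floods)
      }
      if (progress && t %% 500L == 0L) {
        message(sprintf("generation %d: N = %d, mean z = %.3f",
                        start_generation + t, length(z),
                        if (length(z)) mean(z) else NA_real_))
      }
      if (length(z) == 0L) {
        extinct <- TRUE
        extinction_generation <- start_generation + t
        break
      }
    }
  }
  list(
    trajectory = tibble::tibble(
      generation = start_generation + seq_len(nrec) - 1L,
      mean_z = mean_z[seq_len(nrec)],
      sd_z = sd_z[seq_len(nrec)],
      pop_size = pop[seq_len(nrec)]
    ),
    phenotypes = z,
    ages = ages,
    extinct = extinct,
    extinction_generation = extinction_generation,
    flood_events = if (record_floods) {
      dplyr::bind_rows(floods[!vapply(floods, is.null, logical(1))])
    } else {
      NULL
    }
  )
}

#' Run one simulation replicate
#'
#' Seeds the RNG from `config$seed`, initializes `N0` individuals with
#' phenotypes drawn uniformly on \eqn{[0, 1]}, and iterates
#' [step_generation()] for the configured number of generations or until
#' extinction (population size 0), recording the per-generation mean and SD
#' of the phenotype and the population size. The trajectory includes the
#' initial state (generation 0) and is truncated at extinction.
#'
#' @param config A [sim_config()].
#' @param record_floods If `TRUE`, also return a log of every realized flood
#'   (generation and water level).
#' @param keep_state If `TRUE`, return the final phenotype/age vectors (used
#'   to continue a population under a changed regime).
#' @param progress If `TRUE`, message population summaries every 500
#'   generations.
#' @return A `replicate_result`: list with `trajectory` (tibble: generation,
#'   mean_z, sd_z, pop_size), `extinct`, `extinction_generation`, `seed`,
#'   `config`, and optionally `flood_events`, `final_phenotypes`,
#'   `final_ages`.
#' @export
run_replicate <- function(config, record_floods = FALSE, keep_state = FALSE,
                          progress = FALSE) {
  set.seed(config$seed)
  z0 <- stats::runif(config$N0)
  res <- .simulate(z0, integer(config$N0), config, config$generations,
                   record_floods = record_floods, progress = progress)
  out <- list(trajectory = res$trajectory, extinct = res$extinct,
              extinction_generation = res$extinction_generation,
              seed = config$seed, config = config)
  if (record_floods) out$flood_events <- res$flood_events
  if (keep_state) {
    out$final_phenotypes <- res$phenotypes
    out$final_ages <- res$ages
  }
  structure(out, class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(
    "<replicate_result> seed %d, %d generations recorded, %s\n",
    x$seed, nrow(x$trajectory) - 1L,
    if (x$extinct) sprintf("extinct at generation %d", x$extinction_generation)
    else sprintf("extant (N = %d, mean z = %.3f)", last$pop_size, last$mean_z)
  ))
  invisible(x)
}
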