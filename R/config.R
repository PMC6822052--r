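# Constructors and validators for simulation configuration objects.

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

#' Flooding regime
#'
#' The stochastic environment: each breeding attempt (time step within a
#' season) floods with probability `p`; during a flood each nest is
#' independently affected with probability `s` (the scope); realized flood
#' height is `h` (constant by default).
#'
#' @param p Per-attempt flood probability.
#' @param s Scope: per-nest probability of being affected given a flood.
#' @param h Flood height, in phenotype units on \eqn{[0, 1]}.
#' @param flood_height_noise Standard deviation of per-event flood-height
#'   variation (truncated normal centered on `h`, truncated to \eqn{[0, 1]});
#'   0 (default) keeps the height constant.
#' @return An `environment_regime` object.
#' @export
environment_regime <- function(p = 0.05, s = 1, h = 0.4,
                               flood_height_noise = 0) {
  .check_prob(p, "p")
  .check_prob(s, "s")
  .check_prob(h, "h")
  .check_pos(flood_height_noise, "flood_height_noise", strict = FALSE)
  structure(list(p = p, s = s, h = h,
                 flood_height_noise = flood_height_noise),
            class = "environment_regime")
}

#' Life history
#'
#' @param n Number of breeding attempts per lifetime (nesting attempts per
#'   season). More attempts shift fitness accumulation toward the additive
#'   (arithmetic-mean) regime.
#' @param c Clutch constant: maximum clutch size, a measure of the intrinsic
#'   rate of population increase. Baseline 5; 2 models a slow life history.
#' @param overlap If `TRUE`, generations overlap: adults may survive to breed
#'   again next year.
#' @param adult_survival Per-year adult survival probability (used only with
#'   `overlap = TRUE`).
#' @param adult_mortality If `TRUE`, floods kill affected adults whose
#'   phenotype lies below the flood height (otherwise extremes affect only
#'   nestling survival).
#' @return A `life_history` object.
#' @export
life_history <- function(n = 1L, c = 5, overlap = FALSE,
                         adult_survival = 0, adult_mortality = FALSE) {
  clutch <- c
  n <- .check_count(n, "n", min = 1L)
  .check_pos(clutch, "c")
  .check_flag(overlap, "overlap")
  .check_prob(adult_survival, "adult_survival")
  .check_flag(adult_mortality, "adult_mortality")
  structure(list(n = n, c = clutch, overlap = overlap,
                 adult_survival = adult_survival,
                 adult_mortality = adult_mortality),
            class = "life_history")
}

#' Simulation configuration
#'
#' Bundles a flooding regime, a life history, population parameters and run
#' length. Defaults are the baseline model: 5,000 haploid asexual founders,
#' carrying capacity 5,000, mutation probability 0.001 with deviate SD 0.05,
#' flood height 0.4, clutch constant 5, 2,000 generations.
#'
#' @param N0 Initial population size.
#' @param K Carrying capacity (hard cap on recruits per generation).
#' @param m Per-offspring mutation probability.
#' @param m_size Standard deviation of the mutational deviate.
#' @param generations Number of generations to simulate.
#' @param seed Integer RNG seed for the replicate.
#' @param regime An [environment_regime()].
#' @param life_history A [life_history()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(N0 = 5000L, K = 5000L, m = 0.001, m_size = 0.05,
                       generations = 2000L, seed = 1L,
                       regime = environment_regime(),
                       life_history = floodhedge::life_history()) {
  N0 <- .check_count(N0, "N0", min = 0L)
  K <- .check_count(K, "K", min = 0L)
  .check_prob(m, "m")
  .check_pos(m_size, "m_size")
  generations <- .check_count(generations, "generations", min = 0L)
  seed <- .check_count(seed, "seed")
  if (!inherits(regime, "environment_regime")) {
    stop("`regime` must be an environment_regime", call. = FALSE)
  }
  if (!inherits(life_history, "life_history")) {
    stop("`life_history` must be a life_history object", call. = FALSE)
  }
  structure(list(N0 = N0, K = K, m = m, m_size = m_size,
                 generations = generations, seed = seed,
                 regime = regime, life_history = life_history),
            class = "sim_config")
}

# Convenience: copy a config with regime / life-history scalars overridden.
# Used heavily by the sweep machinery.
.config_with <- function(config, p = NULL, s = NULL, h = NULL, n = NULL,
                         seed = NULL, generations = NULL) {
  reg <- config$regime
  lh <- config$life_history
  reg2 <- environment_regime(
    p = if (is.null(p)) reg$p else p,
    s = if (is.null(s)) reg$s else s,
    h = if (is.null(h)) reg$h else h,
    flood_height_noise = reg$flood_height_noise
  )
  lh2 <- life_history(n = if (is.null(n)) lh$n else n, c = lh$c,
                      overlap = lh$overlap,
                      adult_survival = lh$adult_survival,
                      adult_mortality = lh$adult_mortality)
  sim_config(N0 = config$N0, K = config$K, m = config$m,
             m_size = config$m_size,
             generations = if (is.null(generations)) config$generations else generations,
             seed = if (is.null(seed)) config$seed else seed,
             regime = reg2, life_history = lh2)
}

#' Population state
#'
#' @param phenotypes Numeric vector of nest-height phenotypes in \eqn{[0, 1]}.
#' @param ages Integer vector of ages (only meaningful under the
#'   overlapping-generations variant); defaults to all zero.
#' @param generation Generation index.
#' @return A `population_state` object.
#' @export
population_state <- function(phenotypes, ages = NULL, generation = 0L) {
  phenotypes <- as.numeric(phenotypes)
  if (length(phenotypes) && any(phenotypes < 0 | phenotypes > 1)) {
    stop("all phenotypes must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(ages)) ages <- integer(length(phenotypes))
  if (length(ages) != length(phenotypes)) {
    stop("`ages` must match `phenotypes` in length", call. = FALSE)
  }
  structure(list(phenotypes = phenotypes, ages = as.integer(ages),
                 generation = .check_count(generation, "generation")),
            class = "population_state")
}
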