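#' A pair of fitness functions for moderate and extreme conditions
#'
#' Bundles the two fitness curves that define a fluctuating environment:
#' `W_M(z)` under moderate (typical) conditions and `W_E(z)` under extreme
#' conditions, both non-negative on a closed phenotype domain.
#'
#' @param W_M Function of phenotype giving fitness under moderate conditions.
#' @param W_E Function of phenotype giving fitness under extreme conditions.
#' @param domain Closed phenotype interval, default `c(0, 1)`.
#' @return An object of class `fitness_pair`.
#' @seealso [skew_gaussian_pair()] for the standard skewed toy-model pair.
#' @export
fitness_pair <- function(W_M, W_E, domain = c(0, 1)) {
  if (!is.function(W_M) || !is.function(W_E)) {
    stop("`W_M` and `W_E` must be functions of phenotype", call. = FALSE)
  }
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    stop("`domain` must be a finite interval c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(W_M = W_M, W_E = W_E, domain = as.numeric(domain)),
            class = "fitness_pair")
}

#' Skew-Gaussian moderate/extreme fitness pair
#'
#' The standard toy-model landscape: two skew-Gaussian curves with a shared
#' scale and slant but different locations, so that the moderate-condition
#' optimum (near the low end of the phenotype range) performs poorly under
#' extremes and vice versa. Defaults are location 0.1 (moderate) and 0.6
#' (extreme), scale 0.3, slant 5 on the domain \eqn{[0, 1]}.
#'
#' @param loc_moderate,loc_extreme Location parameters of the two curves.
#' @param scale Shared scale parameter (> 0).
#' @param skew Shared slant parameter.
#' @param domain Phenotype domain.
#' @param normalize If `TRUE`, each curve is rescaled so its maximum over the
#'   domain is 1 (argmax-invariant; useful for plotting only).
#' @return A [fitness_pair()].
#' @export
skew_gaussian_pair <- function(loc_moderate = 0.1, loc_extreme = 0.6,
                               scale = 0.3, skew = 5, domain = c(0, 1),
                               normalize = FALSE) {
  pm <- skew_gaussian_params(loc_moderate, scale, skew)
  pe <- skew_gaussian_params(loc_extreme, scale, skew)
  wm <- function(z) skew_gaussian_fitness(z, pm)
  we <- function(z) skew_gaussian_fitness(z, pe)
  if (normalize) {
    grid <- seq(domain[1], domain[2], length.out = 10001L)
    cm <- max(wm(grid))
    ce <- max(we(grid))
    wm_raw <- wm
    we_raw <- we
    wm <- function(z) wm_raw(z) / cm
    we <- function(z) we_raw(z) / ce
  }
  fitness_pair(wm, we, domain)
}

#' Long-term mean-fitness specification
#'
#' Couples a [fitness_pair()] with the probability `p` that a given time step
#' is extreme and the scope `s`, the proportion of the population affected by
#' an extreme event. Together these define the three long-term mean fitness
#' functionals: geometric (fully multiplicative accumulation), arithmetic
#' (fully additive), and mixed.
#'
#' @param pair A [fitness_pair()].
#' @param p Probability of extreme conditions, in \eqn{[0, 1]}.
#' @param s Scope of extreme events, in \eqn{[0, 1]}; default 1 (the whole
#'   population is affected).
#' @return An object of class `mean_fitness_spec`.
#' @export
mean_fitness_spec <- function(pair, p, s = 1) {
  if (!inherits(pair, "fitness_pair")) {
    stop("`pair` must be a fitness_pair", call. = FALSE)
  }
  .check_prob(p, "p")
  .check_prob(s, "s")
  structure(list(pair = pair, p = p, s = s), class = "mean_fitness_spec")
}

#' Geometric mean fitness
#'
#' \eqn{\bar W_G(z) = W_M(z)^{1-p} \cdot W_E(z)^p}: the long-term growth rate
#' when fitness accumulates strictly multiplicatively (coarse-grained
#' environments where extremes hit the whole population at once). A single
#' zero-fitness environment drives it to zero whenever \eqn{p > 0}.
#' `0^0` is treated as 1, so the `p = 0` and `p = 1` limits are exact.
#'
#' @param z Phenotype value(s).
#' @param spec A [mean_fitness_spec()].
#' @return Non-negative value(s).
#' @export
geometric_mean_fitness <- function(z, spec) {
  wm <- spec$pair$W_M(z)
  we <- spec$pair$W_E(z)
  wm^(1 - spec$p) * we^spec$p
}

#' Arithmetic mean fitness
#'
#' \eqn{\bar W_A(z) = (1-p) W_M(z) + p W_E(z)}: the expected per-event payoff,
#' appropriate when reproductive events are independent in time or space
#' (many attempts per lifetime, fine-grained environments).
#'
#' @inheritParams geometric_mean_fitness
#' @return Non-negative value(s).
#' @export
arithmetic_mean_fitness <- function(z, spec) {
  (1 - spec$p) * spec$pair$W_M(z) + spec$p * spec$pair$W_E(z)
}

#' Mixed (additive-multiplicative) mean fitness
#'
#' \eqn{\bar W_{A,G}(z) = W_M(z)^{1-p} \left[(1-s) W_M(z) + s W_E(z)\right]^p}.
#' Scope `s` interpolates between the arithmetic regime (`s = 0`, the mean
#' reduces to \eqn{W_M}) and the geometric regime (`s = 1`, the mean equals
#' [geometric_mean_fitness()]).
#'
#' @inheritParams geometric_mean_fitness
#' @return Non-negative value(s).
#' @export
mixed_mean_fitness <- function(z, spec) {
  wm <- spec$pair$W_M(z)
  we <- spec$pair$W_E(z)
  wm^(1 - spec$p) * ((1 - spec$s) * wm + spec$s * we)^spec$p
}

#' Phenotype maximizing a mean-fitness function
#'
#' Deterministic global argmax: a dense uniform grid over the domain picks the
#' best cell (ties broken toward the smallest phenotype), then a bracketed
#' local search ([stats::optimize()]) refines within one grid step. The grid
#' stage is required because the mean-fitness surfaces are typically bimodal,
#' so a purely local optimizer could latch onto the wrong peak.
#'
#' @param meanfn Function of phenotype, finite on the domain.
#' @param domain Closed interval `c(lo, hi)`.
#' @param grid_step Grid spacing, default `1e-4`.
#' @return The maximizing phenotype (a single number).
#' @export
optimal_phenotype <- function(meanfn, domain = c(0, 1), grid_step = 1e-4) {
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] > domain[2]) {
    stop("`domain` must be a finite interval c(lo, hi)", call. = FALSE)
  }
  if (!is.numeric(grid_step) || grid_step <= 0) {
    stop("`grid_step` must be positive", call. = FALSE)
  }
  if (domain[1] == domain[2]) {
    return(domain[1])
  }
  npts <- max(2L, as.integer(round(diff(domain) / grid_step)) + 1L)
  grid <- seq(domain[1], domain[2], length.out = npts)
  vals <- meanfn(grid)
  if (any(!is.finite(vals))) {
    stop("`meanfn` must be finite on the domain", call. = FALSE)
  }
  i <- which.max(vals)  # first maximum == smallest z on ties
  best_z <- grid[i]
  best_v <- vals[i]
  lo <- max(domain[1], best_z - grid_step)
  hi <- min(domain[2], best_z + grid_step)
  ref <- stats::optimize(meanfn, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (ref$objective > best_v) {
    best_z <- ref$maximum
  }
  best_z
}

#' Tabulate the three mean-fitness functionals over a phenotype grid
#'
#' @param pair A [fitness_pair()].
#' @param p Probability of extreme conditions.
#' @param s Scope.
#' @param grid_step Spacing of the phenotype grid.
#' @return A tibble with columns `z`, `W_M`, `W_E`, `geometric`, `arithmetic`,
#'   `mixed`.
#' @export
theory_table <- function(pair, p, s = 1, grid_step = 0.001) {
  spec <- mean_fitness_spec(pair, p, s)
  npts <- as.integer(round(diff(pair$domain) / grid_step)) + 1L
  z <- seq(pair$domain[1], pair$domain[2], length.out = npts)
  tibble::tibble(
    z = z,
    W_M = pair$W_M(z),
    W_E = pair$W_E(z),
    geometric = geometric_mean_fitness(z, spec),
    arithmetic = arithmetic_mean_fitness(z, spec),
    mixed = mixed_mean_fitness(z, spec)
  )
}

#' Optima of the mean-fitness functionals over (p, s) combinations
#'
#' @param pair A [fitness_pair()].
#' @param p_values,s_values Vectors of extreme-event probabilities and scopes.
#' @param grid_step Argmax grid spacing (see [optimal_phenotype()]).
#' @return Long tibble with columns `statistic` (one of `W_M`, `W_E`,
#'   `geometric`, `arithmetic`, `mixed`), `p`, `s` (`NA` where not
#'   applicable), and `z_opt`.
#' @export
theory_optima <- function(pair, p_values, s_values = 1, grid_step = 1e-4) {
  rows <- list(
    tibble::tibble(statistic = "W_M", p = NA_real_, s = NA_real_,
                   z_opt = optimal_phenotype(pair$W_M, pair$domain, grid_step)),
    tibble::tibble(statistic = "W_E", p = NA_real_, s = NA_real_,
                   z_opt = optimal_phenotype(pair$W_E, pair$domain, grid_step))
  )
  for (p in p_values) {
    spec1 <- mean_fitness_spec(pair, p, 1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      statistic = c("geometric", "arithmetic"), p = p, s = NA_real_,
      z_opt = c(
        optimal_phenotype(function(z) geometric_mean_fitness(z, spec1),
                          pair$domain, grid_step),
        optimal_phenotype(function(z) arithmetic_mean_fitness(z, spec1),
                          pair$domain, grid_step)
      )
    )
    for (s in s_values) {
      spec <- mean_fitness_spec(pair, p, s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        statistic = "mixed", p = p, s = s,
        z_opt = optimal_phenotype(function(z) mixed_mean_fitness(z, spec),
                                  pair$domain, grid_step)
      )
    }
  }
  dplyr::bind_rows(rows)
}
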