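# Sweep and climate-change experiment orchestration.

#' Classify the evolutionary outcome of a surviving population
#'
#' Surviving populations settle on one of two strategies: low nesting (mean
#' phenotype below 0.05; fitness maximization under moderate conditions) or
#' high nesting (mean phenotype above the flood height `h`; conservative
#' bet-hedging). Anything in between — including the boundary values — is
#' `intermediate`.
#'
#' @param mean_z Population mean phenotype(s) in \eqn{[0, 1]}.
#' @param h Flood height against which "high" is judged.
#' @return Character vector in `{"low", "intermediate", "high"}` (`NA` where
#'   `mean_z` is `NA`).
#' @export
classify_outcome <- function(mean_z, h) {
  .check_prob(h, "h")
  if (any(mean_z < 0 | mean_z > 1, na.rm = TRUE)) {
    stop("`mean_z` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(is.na(mean_z), NA_character_,
         ifelse(mean_z < 0.05, "low",
                ifelse(mean_z > h, "high", "intermediate")))
}

#' Parameter-sweep grid
#'
#' Cartesian grid over flood probability, scope, and breeding attempts per
#' lifetime, each cell replicated independently. The default grid spans the
#' regimes where additive vs. multiplicative fitness accumulation dominate.
#'
#' @param p_values Flood probabilities.
#' @param s_values Scopes.
#' @param n_values Breeding-attempt counts.
#' @param replicates Replicates per cell (default 100).
#' @param base_config [sim_config()] supplying everything the grid does not
#'   vary (including `h`, `K`, mutation parameters, and run length).
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(p_values = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                       s_values = c(0.8, 0.9, 1.0),
                       n_values = 1:5,
                       replicates = 100L,
                       base_config = sim_config()) {
  for (p in p_values) .check_prob(p, "p_values")
  for (s in s_values) .check_prob(s, "s_values")
  for (n in n_values) .check_count(n, "n_values", min = 1L)
  replicates <- .check_count(replicates, "replicates", min = 1L)
  if (!inherits(base_config, "sim_config")) {
    stop("`base_config` must be a sim_config", call. = FALSE)
  }
  structure(list(p_values = p_values, s_values = s_values,
                 n_values = n_values, replicates = replicates,
                 base_config = base_config),
            class = "sweep_grid")
}

# Deterministic per-cell, per-replicate seed; a simple LCG-style mix kept
# below 2^31 (exact in double arithmetic since all products < 2^53).
cell_seed <- function(base_seed, cell, replicate) {
  as.integer((as.numeric(base_seed) * 48271 + cell * 69621 +
                replicate * 16807) %% 2147483629) + 1L
}

.grid_cells <- function(grid) {
  cells <- expand.grid(n = grid$n_values, s = grid$s_values,
                       p = grid$p_values, KEEP.OUT.ATTRS = FALSE)
  cells[, c("p", "s", "n")]
}

#' Run the evolutionary-outcome sweep
#'
#' For every (p, s, n) cell of the grid, runs independently seeded replicates
#' of [run_replicate()] and records survival and the final mean phenotype,
#' classified against the (pre-change) flood height of the base regime.
#'
#' @param grid A [sweep_grid()].
#' @param base_seed Seed from which all replicate seeds are derived (default:
#'   the base config's seed).
#' @param progress If `TRUE`, message one line per completed cell.
#' @return A `sweep_result`: list with `replicates` (one tibble row per
#'   replicate: p, s, n, replicate, seed, survived, extinction_generation,
#'   final_size, final_mean_z, outcome) and `summary`
#'   (see [summarize_outcomes()]).
#' @export
run_sweep <- function(grid, base_seed = grid$base_config$seed,
                      progress = FALSE) {
  cells <- .grid_cells(grid)
  h <- grid$base_config$regime$h
  rows <- vector("list", nrow(cells) * grid$replicates)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]
    s <- cells$s[ci]
    n <- cells$n[ci]
    for (r in seq_len(grid$replicates)) {
      seed <- cell_seed(base_seed, ci, r)
      cfg <- .config_with(grid$base_config, p = p, s = s, n = n, seed = seed)
      rep_res <- run_replicate(cfg)
      tr <- rep_res$trajectory
      final <- tr[nrow(tr), ]
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        p = p, s = s, n = n, replicate = r, seed = seed,
        survived = !rep_res$extinct,
        extinction_generation = rep_res$extinction_generation,
        final_size = final$pop_size,
        final_mean_z = final$mean_z,
        outcome = if (rep_res$extinct) NA_character_ else
          classify_outcome(final$mean_z, h)
      )
    }
    if (progress) {
      message(sprintf("cell %d/%d (p=%.2f, s=%.2f, n=%d) done",
                      ci, nrow(cells), p, s, n))
    }
  }
  replicates <- dplyr::bind_rows(rows)
  structure(list(replicates = replicates,
                 summary = summarize_outcomes(replicates),
                 grid = grid, base_seed = base_seed),
            class = "sweep_result")
}

#' Aggregate per-replicate outcomes into per-cell proportions
#'
#' @param rows Tibble of per-replicate results carrying at least `p`, `s`,
#'   `n`, `survived`, and `outcome`.
#' @return Tibble with one row per (p, s, n) cell: replicate count, the
#'   proportion surviving, and — among survivors — the proportions classified
#'   low / intermediate / high (`NaN` when no replicate survived). The three
#'   class proportions sum to 1 wherever survivors exist.
#' @export
summarize_outcomes <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble::tibble(
      p = numeric(0), s = numeric(0), n = integer(0),
      n_replicates = integer(0), prop_surviving = numeric(0),
      prop_low = numeric(0), prop_intermediate = numeric(0),
      prop_high = numeric(0)
    ))
  }
  dplyr::summarise(
    dplyr::group_by(rows, .data$p, .data$s, .data$n),
    n_replicates = dplyr::n(),
    prop_surviving = mean(.data$survived),
    prop_low = mean(.data$outcome[.data$survived] == "low"),
    prop_intermediate = mean(.data$outcome[.data$survived] == "intermediate"),
    prop_high = mean(.data$outcome[.data$survived] == "high"),
    .groups = "drop"
  )
}

#' Climate-change perturbation specification
#'
#' A rapid-onset increase of one flooding-regime parameter: the height
#' (intensity), scope, or frequency of floods, applied after populations have
#' evolved under the baseline regime.
#'
#' @param target One of `"height"`, `"scope"`, `"frequency"`.
#' @param delta Size of the increase (default +0.1).
#' @param change_generation Generation at which the change hits (default
#'   2,000).
#' @param followup_generations How long populations are followed afterwards
#'   (default 200; long enough for change-driven extinction, short enough to
#'   limit confounding background mortality).
#' @return A `climate_change_spec` object.
#' @export
climate_change_spec <- function(target = c("height", "scope", "frequency"),
                                delta = 0.1, change_generation = 2000L,
                                followup_generations = 200L) {
  target <- match.arg(target)
  .check_pos(delta, "delta", strict = FALSE)
  structure(list(
    target = target, delta = delta,
    change_generation = .check_count(change_generation, "change_generation",
                                     min = 1L),
    followup_generations = .check_count(followup_generations,
                                        "followup_generations", min = 0L)
  ), class = "climate_change_spec")
}

#' Apply a climate-change perturbation to a configuration
#'
#' Returns a copy of `config` whose regime has the targeted parameter
#' increased by `delta`; probabilities (`p`, `s`) and the flood height `h`
#' are capped at 1. Everything else is untouched.
#'
#' @param config A [sim_config()].
#' @param spec A [climate_change_spec()].
#' @return The perturbed `sim_config`.
#' @export
apply_climate_change <- function(config, spec) {
  if (!inherits(spec, "climate_change_spec")) {
    stop("`spec` must be a climate_change_spec", call. = FALSE)
  }
  reg <- config$regime
  switch(spec$target,
    height = .config_with(config, h = min(1, reg$h + spec$delta)),
    scope = .config_with(config, s = min(1, reg$s + spec$delta)),
    frequency = .config_with(config, p = min(1, reg$p + spec$delta)),
    stop(sprintf("unknown climate-change target: %s", spec$target),
         call. = FALSE)
  )
}

#' Run the two-stage climate-change experiment
#'
#' Stage 1: each replicate evolves under its cell's baseline regime until
#' `change_generation`. Stage 2: every stage-1 survivor is continued under the
#' perturbed regime for `followup_generations`. Several perturbation specs may
#' be supplied (they must share `change_generation` and
#' `followup_generations`): stage 1 is then run once per replicate and the
#' RNG state is branched identically into each perturbation arm, so stage-1
#' dynamics are bit-identical to an unperturbed run with the same seed and
#' arms differ only through the regime change.
#'
#' Final phenotypes are classified against both the pre-change flood height
#' (the regime the population evolved under) and the post-change height.
#'
#' @param grid A [sweep_grid()].
#' @param specs A [climate_change_spec()] or a list of them.
#' @param base_seed Seed from which replicate seeds are derived.
#' @return A `climate_result`: list with `replicates` (one row per replicate
#'   x perturbation arm) and `summary` (per cell x target: number of stage-1
#'   survivors, relative survival among them, and outcome proportions among
#'   post-change survivors).
#' @export
run_climate_experiment <- function(grid, specs,
                                   base_seed = grid$base_config$seed) {
  if (inherits(specs, "climate_change_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1),
                                    "climate_change_spec"))) {
    stop("`specs` must be one or more climate_change_spec objects",
         call. = FALSE)
  }
  cg <- unique(vapply(specs, `[[`, numeric(1), "change_generation"))
  fg <- unique(vapply(specs, `[[`, numeric(1), "followup_generations"))
  if (length(cg) != 1L || length(fg) != 1L) {
    stop("all specs must share change_generation and followup_generations",
         call. = FALSE)
  }
  cells <- .grid_cells(grid)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]
    s <- cells$s[ci]
    n <- cells$n[ci]
    for (r in seq_len(grid$replicates)) {
      seed <- cell_seed(base_seed, ci, r)
      cfg <- .config_with(grid$base_config, p = p, s = s, n = n, seed = seed,
                          generations = cg)
      set.seed(seed)
      z0 <- stats::runif(cfg$N0)
      s1 <- .simulate(z0, integer(cfg$N0), cfg, cg)
      s1_final <- s1$trajectory[nrow(s1$trajectory), ]
      s1_outcome <- if (s1$extinct) NA_character_ else
        classify_outcome(s1_final$mean_z, cfg$regime$h)
      rng_state <- if (!s1$extinct) get(".Random.seed", envir = globalenv())
      for (spec in specs) {
        cfg2 <- apply_climate_change(cfg, spec)
        if (s1$extinct) {
          post_survived <- NA
          post_mean_z <- NA_real_
        } else {
          assign(".Random.seed", rng_state, envir = globalenv())
          s2 <- .simulate(s1$phenotypes, s1$ages, cfg2,
                          spec$followup_generations,
                          start_generation = cg)
          s2_final <- s2$trajectory[nrow(s2$trajectory), ]
          post_survived <- !s2$extinct
          post_mean_z <- s2_final$mean_z
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          p = p, s = s, n = n, replicate = r, seed = seed,
          target = spec$target, delta = spec$delta,
          stage1_survived = !s1$extinct,
          stage1_mean_z = s1_final$mean_z,
          stage1_outcome = s1_outcome,
          post_survived = post_survived,
          post_mean_z = post_mean_z,
          post_outcome = ifelse(isTRUE(post_survived),
                                classify_outcome(post_mean_z, cfg$regime$h),
                                NA_character_),
          post_outcome_new_h = ifelse(isTRUE(post_survived),
                                      classify_outcome(post_mean_z,
                                                       cfg2$regime$h),
                                      NA_character_)
        )
      }
    }
  }
  replicates <- dplyr::bind_rows(rows)
  structure(list(replicates = replicates,
                 summary = summarize_climate(replicates),
                 grid = grid, specs = specs, base_seed = base_seed),
            class = "climate_result")
}

#' Aggregate climate-experiment replicates
#'
#' Relative survival is defined among the pool of populations that survived
#' to the change: the proportion still extant at the end of the follow-up.
#'
#' @param rows Per-replicate tibble from [run_climate_experiment()].
#' @return Tibble with one row per (p, s, n, target) combination.
#' @export
summarize_climate <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble::tibble(
      p = numeric(0), s = numeric(0), n = integer(0), target = character(0),
      n_replicates = integer(0), n_stage1_survivors = integer(0),
      relative_survival = numeric(0), prop_low = numeric(0),
      prop_intermediate = numeric(0), prop_high = numeric(0)
    ))
  }
  dplyr::summarise(
    dplyr::group_by(rows, .data$p, .data$s, .data$n, .data$target,
                    .data$delta),
    n_replicates = dplyr::n(),
    n_stage1_survivors = sum(.data$stage1_survived),
    relative_survival = mean(.data$post_survived[.data$stage1_survived]),
    prop_low = mean(.data$post_outcome[which(.data$post_survived)] == "low"),
    prop_intermediate =
      mean(.data$post_outcome[which(.data$post_survived)] == "intermediate"),
    prop_high = mean(.data$post_outcome[which(.data$post_survived)] == "high"),
    .groups = "drop"
  )
}
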