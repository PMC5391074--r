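#' Run replicate simulations
#'
#' Runs `replicates` independent simulations of one configuration, replicate
#' `i` seeded with `base_seed + i - 1`, and returns one summary row per
#' replicate.  Replicate-level determinism is the contract: rerunning the
#' same spec reproduces every row regardless of execution order.
#'
#' @param cfg A [smili_config()].
#' @param replicates Number of replicates.
#' @param base_seed Seed of the first replicate.
#' @param window_years Averaging window for the membership summary.
#' @param keep_sims Return the full `smili_sim` objects as an attribute
#'   (memory-heavy; off by default).
#' @return Data frame with one row per replicate: seed, mean PC/co-op
#'   membership, co-op share (%), mean member reliability per form, counts of
#'   dissolutions by form and reason, and survivor maxima.
#' @export
#' @examples
#' run_replicates(smili_preset("reference", years = 2), replicates = 2,
#'                base_seed = 1, window_years = 1)
run_replicates <- function(cfg, replicates = 30L, base_seed = 1L,
                           window_years = 33, keep_sims = FALSE) {
  sims <- vector("list", replicates)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    seed <- base_seed + i - 1L
    sim <- run_simulation(cfg, seed = seed)
    ms <- membership_summary(sim, window_years)
    sr <- surviving_reliability(sim, window_years)
    ev <- sim$events[sim$events$event == "dissolution", ]
    cnt <- function(k, r) sum(ev$kind == k & ev$reason == r)
    final_year <- max(sim$orgs$year, -1)
    surv <- sim$orgs[sim$orgs$year == final_year, , drop = FALSE]
    maxage <- function(k) {
      a <- surv$age[surv$kind == k]
      if (length(a)) max(a) else NA_real_
    }
    rows[[i]] <- data.frame(
      replicate = i, seed = seed,
      pc = ms$pc, coop = ms$coop, inactive = ms$inactive,
      coop_share_pct = ms$coop_share_pct,
      rel_pc = sr[["pc"]], rel_coop = sr[["coop"]],
      pc_diss_capital = cnt("pc", "capital"),
      coop_diss_capital = cnt("coop", "capital"),
      coop_diss_loyalty = cnt("coop", "loyalty"),
      coop_diss_members = cnt("coop", "members"),
      pc_max_survivor_age = maxage("pc"),
      coop_max_survivor_age = maxage("coop"))
    if (keep_sims) sims[[i]] <- sim
  }
  out <- do.call(rbind, rows)
  if (keep_sims) attr(out, "sims") <- sims
  out
}

#' Define an experiment grid
#'
#' The cross-product of the supplied parameter value lists, enumerated
#' deterministically (last factor varying fastest), each cell run with the
#' same replicate/seed plan.
#'
#' @param name Experiment name.
#' @param preset Scenario preset the overrides apply to.
#' @param grid Named list of parameter value vectors (names must be
#'   [smili_config()] arguments, e.g.
#'   `list(initial_loyalty_mean = c(0, 10, 40, 100, 300))`).
#' @param replicates Replicates per cell.
#' @param base_seed Seed of the first replicate of every cell.
#' @param overrides Fixed overrides applied to every cell (e.g. `years`).
#' @return An object of class `smili_experiment_spec`.
#' @export
experiment_spec <- function(name, grid, preset = "full_model",
                            replicates = 30L, base_seed = 1L,
                            overrides = list()) {
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)),
            all(nzchar(names(grid))))
  structure(list(name = name, preset = preset, grid = grid,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), overrides = overrides),
            class = "smili_experiment_spec")
}

#' Run an experiment grid
#'
#' Runs every cell of the spec's parameter grid with the configured number of
#' replicates and returns the per-replicate rows plus a per-cell aggregate
#' (mean, sd and replicate count — never bare means).
#'
#' @param spec An [experiment_spec()].
#' @param window_years Averaging window for the outcome statistics.
#' @return List with `results` (one row per cell x replicate) and `aggregate`
#'   (one row per cell: mean/sd of PC and co-op membership and co-op share,
#'   with `n` replicates).
#' @export
#' @examples
#' sp <- experiment_spec("loyalty", list(initial_loyalty_mean = c(0, 40)),
#'                       replicates = 2, overrides = list(years = 2))
#' res <- run_experiment(sp, window_years = 1)
run_experiment <- function(spec, window_years = 33) {
  stopifnot(inherits(spec, "smili_experiment_spec"))
  cells <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    over <- c(as.list(cells[ci, , drop = FALSE]), spec$overrides)
    cfg <- do.call(smili_preset, c(list(name = spec$preset), over))
    rr <- run_replicates(cfg, spec$replicates, spec$base_seed, window_years)
    res[[ci]] <- cbind(cell = ci, cells[ci, , drop = FALSE],
                       rr, row.names = NULL)
  }
  results <- do.call(rbind, res)
  agg <- do.call(rbind, lapply(split(results, results$cell), function(g) {
    data.frame(g[1, c("cell", names(spec$grid)), drop = FALSE],
               n = nrow(g),
               pc_mean = mean(g$pc), pc_sd = stats::sd(g$pc),
               coop_mean = mean(g$coop), coop_sd = stats::sd(g$coop),
               coop_share_mean = mean(g$coop_share_pct, na.rm = TRUE),
               coop_share_sd = stats::sd(g$coop_share_pct, na.rm = TRUE),
               row.names = NULL)
  }))
  list(name = spec$name, results = results, aggregate = agg)
}

#' Run the validation ladder
#'
#' Reruns the model with complexity added one rung at a time, from the
#' calibrated baseline with annual entry only, through cheating with equal
#' loyalty growth rates, to the full model with the co-op loyalty rate halved
#' (still with homogeneous fishers: reliability 1, skills 0.5, initial
#' loyalty 0).  Reports mean membership per form and co-op dissolution
#' reasons per rung.
#'
#' @param replicates Replicates per rung.
#' @param base_seed Seed of the first replicate.
#' @param years Years per run.
#' @param window_years Averaging window.
#' @return Data frame with one row per rung.
#' @export
run_validation_ladder <- function(replicates = 30L, base_seed = 1L,
                                  years = 100L, window_years = 33) {
  rungs <- list(
    entry_no_cheating = list(name = "entry_no_cheating"),
    entry_cheating_equal_rates = list(name = "entry_cheating_equal_rates"),
    full_model_homogeneous = list(name = "full_model",
                                  reliability_mean = 1.0, reliability_sd = 0,
                                  skills_mean = 0.5, skills_sd = 0,
                                  initial_loyalty_mean = 0,
                                  initial_loyalty_sd = 0)
  )
  out <- lapply(names(rungs), function(nm) {
    cfg <- do.call(smili_preset, c(rungs[[nm]], list(years = years)))
    rr <- run_replicates(cfg, replicates, base_seed, window_years)
    data.frame(rung = nm,
               pc = mean(rr$pc), pc_sd = stats::sd(rr$pc),
               coop = mean(rr$coop), coop_sd = stats::sd(rr$coop),
               coop_share_pct = mean(rr$coop_share_pct, na.rm = TRUE),
               coop_diss_capital = mean(rr$coop_diss_capital),
               coop_diss_loyalty = mean(rr$coop_diss_loyalty),
               coop_diss_members = mean(rr$coop_diss_members),
               n = nrow(rr))
  })
  do.call(rbind, out)
}
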