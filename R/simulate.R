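#' Run one fishery simulation
#'
#' Advances the community through `cfg$years` years of 365 daily cycles
#' (crew selection, lending, fishing, cheating, trading, loyalty settlement,
#' contract renewal, dissolution, stock update) plus the annual entry of one
#' buyer and one co-op where enabled, and collects daily membership and
#' biomass series, an annual organization census, and a reason-coded
#' entry/dissolution ledger.
#'
#' Two engines are provided.  `"cpp"` (default) is the compiled production
#' engine; `"r"` is a pure-R reference implementation of the identical
#' semantics.  Both consume R's random-number stream in the same documented
#' order, so the same `(config, seed)` pair yields bit-identical results from
#' either engine — a property the test suite relies on.
#'
#' @param cfg A [smili_config()] or [smili_preset()].
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `smili_sim`: a list with `daily` (one row per
#'   day: biomass, harvest, members per form, patrons, inactive, living
#'   organizations, money flows, capital totals, mean member reliability per
#'   form), `orgs` (end-of-year census of living organizations), `events`
#'   (entries and reason-coded dissolutions with ages), `config` and `seed`.
#' @seealso [membership_summary()], [persistence_summary()],
#'   [run_replicates()], [run_experiment()]
#' @export
#' @examples
#' sim <- run_simulation(smili_preset("reference", years = 3), seed = 1)
#' summary(sim)
run_simulation <- function(cfg, seed, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_config(cfg)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  raw <- if (engine == "cpp") .run_engine_cpp(unclass(cfg))
         else run_engine_r(cfg)
  assemble_result(raw, cfg, seed, engine)
}

assemble_result <- function(raw, cfg, seed, engine) {
  daily <- as.data.frame(raw$daily)
  names(daily) <- DAILY_COLS
  census <- as.data.frame(raw$census)
  if (ncol(census) == 0)
    census <- as.data.frame(matrix(numeric(0), 0, length(CENSUS_COLS)))
  names(census) <- CENSUS_COLS
  census$kind <- c("pc", "coop")[census$kind]
  events <- as.data.frame(raw$events)
  if (ncol(events) == 0)
    events <- as.data.frame(matrix(numeric(0), 0, length(EVENT_COLS)))
  names(events) <- EVENT_COLS
  events$kind <- c("pc", "coop")[events$kind]
  events$event <- c("entry", "dissolution", "entry_skipped")[events$event]
  events$reason <- c(NA, "capital", "loyalty", "members")[events$reason + 1]
  events$age[events$age < 0] <- NA
  events$founder[events$founder == 0] <- NA
  structure(list(daily = daily, orgs = census, events = events,
                 config = cfg, seed = seed, engine = engine),
            class = "smili_sim")
}

#' @export
print.smili_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<smili_sim> %d years, seed %s, engine %s\n",
              cfg$years, format(x$seed), x$engine))
  nd <- nrow(x$daily)
  last <- x$daily[nd, ]
  cat(sprintf("  final day: %d PC / %d co-op members, %d inactive, biomass %.1f (K = %g)\n",
              as.integer(last$pc_members), as.integer(last$coop_members),
              as.integer(last$inactive), last$biomass, cfg$K))
  diss <- x$events[x$events$event == "dissolution", ]
  cat(sprintf("  entries: %d | dissolutions: %d (%s)\n",
              sum(x$events$event == "entry"), nrow(diss),
              if (nrow(diss)) paste(names(table(diss$reason)),
                                    table(diss$reason), collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
summary.smili_sim <- function(object, window_years = NULL, ...) {
  cfg <- object$config
  if (is.null(window_years)) window_years <- min(33L, cfg$years)
  ms <- membership_summary(object, window_years)
  ps <- persistence_summary(object)
  out <- list(membership = ms, persistence = ps,
              years = cfg$years, window_years = window_years,
              final_biomass = object$daily$biomass[nrow(object$daily)],
              K = cfg$K)
  class(out) <- "summary.smili_sim"
  out
}

#' @export
print.summary.smili_sim <- function(x, ...) {
  m <- x$membership
  cat(sprintf("Mean membership over the last %d of %d years:\n",
              x$window_years, x$years))
  cat(sprintf("  PC: %.1f   co-op: %.1f   inactive: %.1f   co-op share of members: %s\n",
              m$pc, m$coop, m$inactive,
              if (is.nan(m$coop_share_pct)) "n/a"
              else sprintf("%.1f%%", m$coop_share_pct)))
  cat(sprintf("Final biomass: %.1f (K = %g)\n", x$final_biomass, x$K))
  if (nrow(x$persistence$dissolved)) {
    cat("Mean age at dissolution by form and reason:\n")
    print(x$persistence$dissolved, row.names = FALSE)
  } else cat("No dissolutions.\n")
  if (nrow(x$persistence$survivors)) {
    cat("Survivors at the end of the run:\n")
    print(x$persistence$survivors, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a simulation
#'
#' Two-panel base-graphics display: daily membership per governance form and
#' the stock biomass trajectory (with the carrying capacity marked).
#'
#' @param x A `smili_sim`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.smili_sim <- function(x, ...) {
  d <- x$daily
  yrs <- d$day / 365
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(yrs, d$pc_members, type = "l", col = "steelblue",
                 ylim = c(0, max(d$pc_members, d$coop_members, 1)),
                 xlab = "year", ylab = "active fishers", ...)
  graphics::lines(yrs, d$coop_members, col = "firebrick")
  graphics::legend("topleft", c("PC", "co-op"), lty = 1, bty = "n",
                   col = c("steelblue", "firebrick"))
  graphics::plot(yrs, d$biomass, type = "l", col = "darkgreen",
                 xlab = "year", ylab = "biomass",
                 ylim = c(0, max(d$biomass, x$config$K)))
  graphics::abline(h = x$config$K / 2, lty = 3)
  invisible(x)
}
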