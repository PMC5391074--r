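#' Membership summary over the final window
#'
#' Mean daily membership per governance form over the last `window_years`
#' of the run (the outcome statistic of interest: quasi-stable patterns,
#' not initial transients), plus the co-op share of organized fishers in
#' percent.
#'
#' @param sim A `smili_sim`.
#' @param window_years Averaging window (default 33, capped at the run
#'   length); longer than the run is an error.
#' @return List with `pc`, `coop`, `inactive` (mean fishers) and
#'   `coop_share_pct` = 100 * coop / (coop + pc) (NaN when no fisher was
#'   organized in the window).
#' @export
#' @examples
#' sim <- run_simulation(smili_preset("reference", years = 2), seed = 1)
#' membership_summary(sim, window_years = 1)
membership_summary <- function(sim, window_years = 33) {
  stopifnot(inherits(sim, "smili_sim"))
  d <- sim$daily
  nd <- nrow(d)
  wd <- as.integer(window_years * 365)
  if (wd > nd) stop("window longer than the simulated period", call. = FALSE)
  w <- d[(nd - wd + 1L):nd, ]
  pc <- mean(w$pc_members)
  coop <- mean(w$coop_members)
  list(pc = pc, coop = coop, inactive = mean(w$inactive),
       coop_share_pct = if (pc + coop > 0) 100 * coop / (pc + coop) else NaN)
}

#' Persistence (age) summary
#'
#' Ages of organizations from establishment to dissolution, split by form and
#' dissolution reason, plus the ages of the organizations still alive at the
#' end of the run.
#'
#' @param sim A `smili_sim`.
#' @return List of two data frames: `dissolved` (kind, reason, n, mean_age,
#'   max_age) and `survivors` (kind, n, mean_age, max_age).
#' @export
persistence_summary <- function(sim) {
  stopifnot(inherits(sim, "smili_sim"))
  ev <- sim$events[sim$events$event == "dissolution", ]
  dissolved <- if (nrow(ev)) {
    agg <- aggregate(ev$age, by = list(kind = ev$kind, reason = ev$reason),
                     FUN = function(a) c(n = length(a), mean_age = mean(a),
                                         max_age = max(a)))
    data.frame(kind = agg$kind, reason = agg$reason,
               n = agg$x[, "n"], mean_age = agg$x[, "mean_age"],
               max_age = agg$x[, "max_age"])
  } else data.frame(kind = character(0), reason = character(0),
                    n = numeric(0), mean_age = numeric(0),
                    max_age = numeric(0))
  final_year <- max(sim$orgs$year, -1)
  surv <- sim$orgs[sim$orgs$year == final_year, , drop = FALSE]
  survivors <- if (nrow(surv)) {
    agg <- aggregate(surv$age, by = list(kind = surv$kind),
                     FUN = function(a) c(n = length(a), mean_age = mean(a),
                                         max_age = max(a)))
    data.frame(kind = agg$kind, n = agg$x[, "n"],
               mean_age = agg$x[, "mean_age"], max_age = agg$x[, "max_age"])
  } else data.frame(kind = character(0), n = numeric(0),
                    mean_age = numeric(0), max_age = numeric(0))
  list(dissolved = dissolved, survivors = survivors)
}

#' Mean reliability of active fishers by governance form
#'
#' The daily mean reliability trait of the fishers currently active in each
#' form, time-averaged over the final window.  Days on which a form has no
#' active fishers are ignored; a form empty throughout the window is reported
#' as `NA` (not 0).
#'
#' @param sim A `smili_sim`.
#' @param window_years Averaging window.
#' @return Named numeric vector `c(pc = , coop = )`.
#' @export
surviving_reliability <- function(sim, window_years = 33) {
  stopifnot(inherits(sim, "smili_sim"))
  d <- sim$daily
  nd <- nrow(d)
  wd <- as.integer(window_years * 365)
  if (wd > nd) stop("window longer than the simulated period", call. = FALSE)
  w <- d[(nd - wd + 1L):nd, ]
  avg <- function(v) {
    v <- v[!is.nan(v) & !is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  c(pc = avg(w$mean_rel_pc), coop = avg(w$mean_rel_coop))
}

#' Cumulative dissolution counts by reason
#'
#' The accumulated number of organizations of each form that dissolved for
#' each reason (capital, loyalty, members) up to each year; monotone
#' nondecreasing by construction.
#'
#' @param sim A `smili_sim`.
#' @return Data frame: kind, reason, year, cumulative count.
#' @export
dissolution_ledger <- function(sim) {
  stopifnot(inherits(sim, "smili_sim"))
  ev <- sim$events[sim$events$event == "dissolution", ]
  if (!nrow(ev))
    return(data.frame(kind = character(0), reason = character(0),
                      year = numeric(0), cumulative = numeric(0)))
  out <- do.call(rbind, lapply(split(ev, list(ev$kind, ev$reason),
                                     drop = TRUE), function(g) {
    tab <- table(factor(g$year, levels = 0:max(sim$daily$year)))
    data.frame(kind = g$kind[1], reason = g$reason[1],
               year = as.numeric(names(tab)), cumulative = cumsum(tab))
  }))
  rownames(out) <- NULL
  out
}
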