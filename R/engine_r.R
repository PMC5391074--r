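# Pure-R reference engine.
#
# This is the normative implementation of the daily cycle: the C++ production
# engine mirrors it operation by operation, consuming R's global RNG stream
# in the identical documented order, so that both engines produce
# bit-identical trajectories from the same seed (asserted in the test suite).
#
# RNG consumption order (fixed contract, per run):
#   init:  n normal draws (reliability), n normal draws (skills), then per
#          initial buyer: known-set sample, member sample; per initial co-op:
#          member sample, member loyalty normals.
#   day:   [entry day] buyer: known sample, member sample; co-op: member
#          sample, loyalty normals.  crew selection round B: one uniform for
#          the fisher, one for the buyer.  [stochastic regime] one normal for
#          the day's catch factor.  [cheating] per active fisher in id order:
#          alpha then beta.  settlement: one uniform per cheater with >= 1
#          other living organization.
# Samples without replacement use a partial Fisher-Yates with sequential
# uniform draws (fy_sample), identical in both engines.

# metric columns of the daily matrix
DAILY_COLS <- c("day", "year", "biomass", "harvest", "pc_members",
                "coop_members", "patrons", "inactive", "n_buyers", "n_coops",
                "money_in", "money_out", "write_off", "fisher_capital",
                "org_capital", "mean_rel_pc", "mean_rel_coop")
CENSUS_COLS <- c("year", "org_id", "kind", "age", "capital", "capital_total",
                 "loyalty", "members")
EVENT_COLS <- c("year", "org_id", "kind", "event", "reason", "age", "founder")

# partial Fisher-Yates sample of m elements from pool, one uniform per pick
fy_sample <- function(pool, m) {
  n <- length(pool)
  m <- min(m, n)
  if (m == 0L) return(integer(0))
  for (k in seq_len(m)) {
    j <- k + as.integer(floor(stats::runif(1) * (n - k + 1)))
    if (j > n) j <- n
    tmp <- pool[k]; pool[k] <- pool[j]; pool[j] <- tmp
  }
  pool[seq_len(m)]
}

#' Initialize a fishery state
#'
#' Samples the population and creates the initial organizations, consuming
#' the current RNG stream.  The returned state is a mutable environment that
#' [step_day()] advances in place; it is the substrate of the pure-R
#' reference engine (see [run_simulation()] with `engine = "r"`).
#'
#' @param cfg A [smili_config()].
#' @return An environment of class `smili_state`.
#' @export
#' @examples
#' set.seed(1)
#' st <- init_state(smili_preset("reference", years = 1))
#' sum(st$org > 0)   # 50 fishers committed to the 10 initial organizations
init_state <- function(cfg) {
  validate_config(cfg)
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  n <- cfg$n_fishers
  e$rel <- clip(stats::rnorm(n, cfg$reliability_mean, cfg$reliability_sd), 0, 1)
  e$skl <- pmax(stats::rnorm(n, cfg$skills_mean, cfg$skills_sd), 0)
  e$loyalty <- rep(0, n)
  e$capital <- rep(cfg$initial_capital, n)
  e$org <- rep(0L, n)
  e$patron <- rep(FALSE, n)
  e$cheats <- rep(0L, n)
  e$o_kind <- integer(0)       # 1 = pc, 2 = coop
  e$o_alive <- logical(0)
  e$o_capital <- numeric(0)
  e$o_entry_year <- integer(0)
  e$o_patron <- integer(0)
  e$o_known <- list()
  e$delivered <- numeric(0)
  e$N <- cfg$N0
  e$day <- 0L
  e$money_in <- 0; e$money_out <- 0; e$write_off <- 0
  e$events <- list()
  e$census <- list()
  e$daily <- matrix(NA_real_, 365L * cfg$years, length(DAILY_COLS),
                    dimnames = list(NULL, DAILY_COLS))
  for (i in seq_len(cfg$n_init_buyers)) add_buyer(e, founder = 0L, year = 0L)
  for (i in seq_len(cfg$n_init_coops)) add_coop(e, year = 0L)
  class(e) <- "smili_state"
  e
}

inactive_ids <- function(e) which(e$org == 0L)

members_of <- function(e, oid) which(e$org == oid & !e$patron)

add_buyer <- function(e, founder, year) {
  cfg <- e$cfg
  oid <- length(e$o_kind) + 1L
  cap <- cfg$buyer_endowment
  e$money_in <- e$money_in + cfg$buyer_endowment
  if (founder > 0L) {
    cap <- cap + e$capital[founder]
    e$capital[founder] <- 0
    e$patron[founder] <- TRUE
    e$org[founder] <- oid
  }
  e$o_kind <- c(e$o_kind, 1L)
  e$o_alive <- c(e$o_alive, TRUE)
  e$o_capital <- c(e$o_capital, cap)
  e$o_entry_year <- c(e$o_entry_year, as.integer(year))
  e$o_patron <- c(e$o_patron, as.integer(founder))
  nk <- as.integer(round(cfg$known_fraction * cfg$n_fishers))
  e$o_known[[oid]] <- fy_sample(seq_len(cfg$n_fishers), nk)
  members <- fy_sample(inactive_ids(e), cfg$entry_members)
  e$org[members] <- oid
  e$loyalty[members] <- 0      # no loyalty with a new buyer
  oid
}

add_coop <- function(e, year) {
  cfg <- e$cfg
  oid <- length(e$o_kind) + 1L
  e$o_kind <- c(e$o_kind, 2L)
  e$o_alive <- c(e$o_alive, TRUE)
  e$o_capital <- c(e$o_capital, 0)   # pot starts empty; fee-funded
  e$o_entry_year <- c(e$o_entry_year, as.integer(year))
  e$o_patron <- c(e$o_patron, 0L)
  e$o_known[[oid]] <- integer(0)
  members <- fy_sample(inactive_ids(e), cfg$entry_members)
  e$org[members] <- oid
  # history of working together: initial loyalty, clipped at 0
  e$loyalty[members] <- pmax(stats::rnorm(length(members),
                                          cfg$initial_loyalty_mean,
                                          cfg$initial_loyalty_sd), 0)
  oid
}

log_event <- function(e, year, org_id, kind, event, reason = 0L, age = -1L,
                      founder = 0L) {
  e$events[[length(e$events) + 1L]] <-
    as.numeric(c(year, org_id, kind, event, reason, age, founder))
}

#' Annual entry of one buyer and one co-op
#'
#' On the first day of each year the richest inactive fisher (ties broken by
#' lowest id) founds a new patron-client organization with
#' `entry_members` random inactive fishers and his personal capital plus the
#' entry endowment; a new co-op of `entry_members` random inactive fishers
#' forms with an empty pot and member loyalties drawn from the
#' initial-loyalty distribution.  Either entry is skipped (and logged) when
#' too few inactive fishers remain.  Every entrant receives the fixed market
#' share.
#'
#' @param e A `smili_state`.
#' @param year Current simulation year (0-based).
#' @return The state, invisibly.
#' @export
annual_entry <- function(e, year) {
  cfg <- e$cfg
  pool <- inactive_ids(e)
  if (length(pool) >= cfg$entry_members + 1L) {
    founder <- pool[which.max(e$capital[pool])]   # first max = lowest id
    oid <- add_buyer(e, founder, year)
    log_event(e, year, oid, 1L, 1L, founder = founder)
  } else {
    log_event(e, year, 0L, 1L, 3L)
  }
  pool <- inactive_ids(e)
  if (length(pool) >= cfg$entry_members) {
    oid <- add_coop(e, year)
    log_event(e, year, oid, 2L, 1L)
  } else {
    log_event(e, year, 0L, 2L, 3L)
  }
  invisible(e)
}

under_supplied <- function(e, oid) {
  mem <- members_of(e, oid)
  expected <- e$cfg$q * e$N * sum(e$skl[mem])
  expected < e$cfg$market_share
}

#' Morning crew selection by the buyers
#'
#' Alternating recruitment rounds: (A) every under-supplied buyer, in id
#' order, signs the highest-reputation inactive fisher among those it knows;
#' (B) one uniformly random inactive fisher approaches one uniformly random
#' under-supplied buyer and is accepted.  Rounds alternate until no buyer is
#' under-supplied or no inactive fishers remain.  A buyer counts as
#' under-supplied while the expected delivery of its current crew at today's
#' stock level, \eqn{q N \sum s_i}, falls short of its market share (at low
#' abundance buyers therefore take on more and more fishers).  New recruits
#' start at loyalty 0.  Co-ops have fixed membership and never recruit.
#'
#' @param e A `smili_state`.
#' @return The state, invisibly.
#' @export
select_crews <- function(e) {
  buyers <- which(e$o_alive & e$o_kind == 1L)
  if (length(buyers) == 0L) return(invisible(e))
  repeat {
    # round A: targeted recruitment through the known network
    for (b in buyers) {
      if (!under_supplied(e, b)) next
      cand <- e$o_known[[b]]
      cand <- cand[e$org[cand] == 0L]
      if (length(cand) == 0L) next
      cand <- sort(cand)                       # id order for tie-breaking
      rep_score <- e$rel[cand] * e$skl[cand]
      pick <- cand[which.max(rep_score)]
      e$org[pick] <- b
      e$loyalty[pick] <- 0
    }
    und <- buyers[vapply(buyers, function(b) under_supplied(e, b), logical(1))]
    pool <- inactive_ids(e)
    if (length(und) == 0L || length(pool) == 0L) break
    # round B: a random inactive fisher approaches a random needy buyer
    fi <- 1L + as.integer(floor(stats::runif(1) * length(pool)))
    if (fi > length(pool)) fi <- length(pool)
    bi <- 1L + as.integer(floor(stats::runif(1) * length(und)))
    if (bi > length(und)) bi <- length(und)
    f <- pool[fi]; b <- und[bi]
    e$org[f] <- b
    e$loyalty[f] <- 0
    und <- buyers[vapply(buyers, function(b) under_supplied(e, b), logical(1))]
    if (length(und) == 0L || length(inactive_ids(e)) == 0L) break
  }
  invisible(e)
}

#' End-of-day contract renewal by a buyer
#'
#' While the day's delivered catch exceeds the buyer's market share by more
#' than one average member's catch, the member with the least loyalty (ties
#' broken by lowest id) is dismissed and becomes inactive; subsequent
#' dismissals compare the projected delivery of the remaining crew at the
#' same per-member average.  Dismissed fishers lose their built-up loyalty
#' (it is specific to the relationship).
#'
#' @param e A `smili_state`.
#' @param oid Buyer organization id.
#' @return The state, invisibly.
#' @export
renew_contracts <- function(e, oid) {
  mem <- members_of(e, oid)
  k <- length(mem)
  if (k == 0L) return(invisible(e))
  avg <- e$delivered[oid] / k
  if (avg <= 0) return(invisible(e))
  while (k > 0L && k * avg > e$cfg$market_share + avg) {
    mem <- members_of(e, oid)
    drop <- mem[which.min(e$loyalty[mem])]     # first min = lowest id
    e$org[drop] <- 0L
    e$loyalty[drop] <- 0
    k <- k - 1L
  }
  invisible(e)
}

#' Expel co-op members whose loyalty is exhausted
#'
#' Members whose loyalty has been eroded to zero (by repeated cheating) leave
#' the co-op and become inactive.
#'
#' @param e A `smili_state`.
#' @param oid Co-op organization id.
#' @return The state, invisibly.
#' @export
expel_member <- function(e, oid) {
  mem <- members_of(e, oid)
  bad <- mem[e$loyalty[mem] <= 0]
  if (length(bad)) {
    e$org[bad] <- 0L
    e$loyalty[bad] <- 0
  }
  invisible(e)
}

dissolve_org <- function(e, oid, year, reason) {
  mem <- members_of(e, oid)
  residual <- e$o_capital[oid]
  if (e$o_kind[oid] == 2L && residual > 0 && length(mem) > 0L) {
    # the pot is the members' shared asset: liquidate it evenly
    e$capital[mem] <- e$capital[mem] + residual / length(mem)
    residual <- 0
  }
  e$write_off <- e$write_off + residual
  e$org[mem] <- 0L
  e$loyalty[mem] <- 0
  p <- e$o_patron[oid]
  if (p > 0L) {
    e$patron[p] <- FALSE
    e$org[p] <- 0L
  }
  e$o_alive[oid] <- FALSE
  e$o_capital[oid] <- 0
  log_event(e, year, oid, e$o_kind[oid], 2L,
            reason = c(capital = 1L, loyalty = 2L, members = 3L)[[reason]],
            age = as.integer(year) - e$o_entry_year[oid])
  invisible(e)
}

#' End-of-day dissolution check
#'
#' A buyer goes out of business when its capital is negative.  A co-op
#' dissolves when its capital — the shared pot plus the members' summed
#' personal capital, the co-op being an association whose assets are its
#' members' — is negative (reason `capital`), when its members' summed
#' loyalty is non-positive (reason `loyalty`), or when fewer than `min_size`
#' members remain (reason `members`); when several conditions co-occur the
#' reported reason follows the precedence capital > loyalty > members.  All
#' fishers of a dissolved organization become inactive immediately; a
#' dissolving co-op's positive pot is liquidated evenly to its members, and a
#' dissolved buyer's founder rejoins the fisher pool.
#'
#' @param e A `smili_state`.
#' @param year Current simulation year.
#' @return The state, invisibly.
#' @export
dissolution_check <- function(e, year) {
  for (oid in which(e$o_alive)) {
    if (e$o_kind[oid] == 1L) {
      if (e$o_capital[oid] < 0) dissolve_org(e, oid, year, "capital")
    } else {
      mem <- members_of(e, oid)
      # co-op capital is the members' aggregate: pot + sum of member capital
      if (e$o_capital[oid] + sum(e$capital[mem]) < 0) {
        dissolve_org(e, oid, year, "capital")
      } else if (sum(e$loyalty[mem]) <= 0) {
        dissolve_org(e, oid, year, "loyalty")
      } else if (length(mem) < e$cfg$min_size) {
        dissolve_org(e, oid, year, "members")
      }
    }
  }
  invisible(e)
}

#' Advance the fishery by one day
#'
#' Executes the daily cycle in fixed order: annual entry (first day of the
#' year) -> crew selection -> loan provision -> fishing -> cheating decisions
#' -> trade settlement and loyalty update -> contract renewal and expulsion
#' -> dissolution check -> stock update -> metric recording.
#'
#' @param e A `smili_state` created by [init_state()].
#' @return The state, invisibly.
#' @export
step_day <- function(e) {
  cfg <- e$cfg
  day <- e$day
  year <- day %/% 365L
  doy <- day %% 365L

  if (doy == 0L && cfg$entry_enabled) annual_entry(e, year)
  e$delivered <- numeric(length(e$o_kind))

  select_crews(e)

  # loans
  alive <- which(e$o_alive)
  for (oid in alive) {
    nb <- length(members_of(e, oid))
    e$o_capital[oid] <- e$o_capital[oid] - cfg$fishing_cost * nb
    e$money_out <- e$money_out + cfg$fishing_cost * nb
  }

  # fishing
  factor <- 1
  if (cfg$regime == "stochastic") {
    sdlog <- sqrt(log(1 + cfg$stochastic_cv * cfg$stochastic_cv))
    factor <- exp(stats::rnorm(1, -0.5 * sdlog * sdlog, sdlog))
  }
  af <- which(e$org > 0L & !e$patron)
  catch <- cfg$q * e$skl[af] * e$N * factor
  s <- sum(catch)
  if (s > e$N && s > 0) catch <- catch * (e$N / s)
  harvest <- sum(catch)

  # cheating decisions (alpha then beta per fisher, id order)
  cheat <- rep(FALSE, length(af))
  if (cfg$cheating_enabled && length(af) > 0L) {
    as_printed <- cfg$cheat_rule_variant == "as_printed"
    h <- cfg$loyalty_half_saturation
    for (k in seq_along(af)) {
      i <- af[k]
      a <- stats::runif(1)
      b <- stats::runif(1)
      idx <- e$loyalty[i] / (e$loyalty[i] + h)
      gate <- if (as_printed) e$rel[i] > a else e$rel[i] < a
      cheat[k] <- gate && idx < b
    }
  }

  # settlement and loyalty; decay scales with the form's own growth rate so
  # both forms erode loyalty at the same multiple of the rate they build it
  p <- cfg$price; phi <- cfg$beach_price_fraction; cost <- cfg$fishing_cost
  g_coop <- cfg$loyalty_growth * cfg$coop_rate_fraction
  d_pc <- cfg$loyalty_decay
  d_coop <- cfg$loyalty_decay * cfg$coop_rate_fraction
  for (k in seq_along(af)) {
    i <- af[k]
    home <- e$org[i]
    ci <- catch[k]
    if (cheat[k]) {
      others <- which(e$o_alive)
      others <- others[others != home]
      if (length(others) > 0L) {
        oi <- 1L + as.integer(floor(stats::runif(1) * length(others)))
        if (oi > length(others)) oi <- length(others)
        e$o_capital[others[oi]] <- e$o_capital[others[oi]] + (1 - phi) * p * ci
        e$money_in <- e$money_in + p * ci
      } else {
        e$money_in <- e$money_in + phi * p * ci
      }
      e$capital[i] <- e$capital[i] + phi * p * ci
      di <- if (e$o_kind[home] == 2L) d_coop else d_pc
      e$loyalty[i] <- max(0, e$loyalty[i] - di)
      e$cheats[i] <- e$cheats[i] + 1L
    } else if (e$o_kind[home] == 1L) {
      value <- p * ci
      beach <- phi * value
      repay <- min(cost, beach)
      e$capital[i] <- e$capital[i] + beach - repay
      e$o_capital[home] <- e$o_capital[home] + (1 - phi) * value + repay
      e$money_in <- e$money_in + value
      e$delivered[home] <- e$delivered[home] + ci
      e$loyalty[i] <- e$loyalty[i] + cfg$loyalty_growth
    } else {
      value <- p * ci
      repay <- min(cost, value)
      e$capital[i] <- e$capital[i] + value - repay - cfg$membership_fee
      e$o_capital[home] <- e$o_capital[home] + repay + cfg$membership_fee
      if (e$capital[i] > cfg$capital_threshold) {
        contrib <- cfg$contribution_rate * e$capital[i]
        e$capital[i] <- e$capital[i] - contrib
        e$o_capital[home] <- e$o_capital[home] + contrib
      }
      e$money_in <- e$money_in + value
      e$delivered[home] <- e$delivered[home] + ci
      e$loyalty[i] <- e$loyalty[i] + g_coop
    }
  }

  # renewal, expulsion, dissolution
  for (oid in which(e$o_alive & e$o_kind == 1L)) renew_contracts(e, oid)
  for (oid in which(e$o_alive & e$o_kind == 2L)) expel_member(e, oid)
  dissolution_check(e, year)

  # stock update
  amp <- if (cfg$regime == "seasonal") cfg$seasonal_amplitude else 0
  Kt <- cfg$K * (1 + amp * sin(2 * pi * doy / 365))
  e$N <- max(0, e$N + cfg$r * e$N * (1 - e$N / Kt) - harvest)

  record_day(e, day, year, harvest)
  if (doy == 364L) record_census(e, year)
  e$money_in <- 0; e$money_out <- 0; e$write_off <- 0
  e$day <- day + 1L
  invisible(e)
}

record_day <- function(e, day, year, harvest) {
  act <- e$org > 0L & !e$patron
  kind_of <- function(kk) act & e$o_kind[pmax(e$org, 1L)] == kk
  is_pc <- e$org > 0L & !e$patron & e$o_kind[pmax(e$org, 1L)] == 1L
  is_co <- e$org > 0L & !e$patron & e$o_kind[pmax(e$org, 1L)] == 2L
  npc <- sum(is_pc); nco <- sum(is_co); npat <- sum(e$patron)
  mr_pc <- if (npc > 0L) sum(e$rel[is_pc]) / npc else NaN
  mr_co <- if (nco > 0L) sum(e$rel[is_co]) / nco else NaN
  e$daily[day + 1L, ] <- c(day, year, e$N, harvest, npc, nco, npat,
                           e$cfg$n_fishers - npc - nco - npat,
                           sum(e$o_alive & e$o_kind == 1L),
                           sum(e$o_alive & e$o_kind == 2L),
                           e$money_in, e$money_out, e$write_off,
                           sum(e$capital),
                           sum(e$o_capital[e$o_alive]),
                           mr_pc, mr_co)
}

record_census <- function(e, year) {
  for (oid in which(e$o_alive)) {
    mem <- members_of(e, oid)
    cap_tot <- e$o_capital[oid] +
      if (e$o_kind[oid] == 2L) sum(e$capital[mem]) else 0
    e$census[[length(e$census) + 1L]] <-
      as.numeric(c(year, oid, e$o_kind[oid], year - e$o_entry_year[oid],
                   e$o_capital[oid], cap_tot, sum(e$loyalty[mem]),
                   length(mem)))
  }
}

# run the R engine and return the raw result (same layout as the C++ engine)
run_engine_r <- function(cfg) {
  e <- init_state(cfg)
  total <- 365L * cfg$years
  for (d in seq_len(total)) step_day(e)
  list(daily = e$daily,
       census = if (length(e$census)) do.call(rbind, e$census)
                else matrix(numeric(0), 0, length(CENSUS_COLS)),
       events = if (length(e$events)) do.call(rbind, e$events)
                else matrix(numeric(0), 0, length(EVENT_COLS)))
}
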