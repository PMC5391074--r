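# state-level governance and demography operations on crafted states

empty_pool_state <- function(...) {
  # a community with no organizations: everyone inactive
  cfg <- smili_config(n_init_buyers = 0, n_init_coops = 0, years = 1, ...)
  set.seed(5)
  init_state(cfg)
}

test_that("annual entry creates one buyer (richest founder) and one co-op", {
  e <- empty_pool_state()
  e$capital[37] <- 99   # the richest inactive fisher founds the PC
  annual_entry(e, year = 0)
  expect_equal(e$o_kind, c(1L, 2L))
  expect_equal(e$o_patron[1], 37L)
  expect_true(e$patron[37])
  expect_equal(e$org[37], 1L)
  expect_equal(e$o_capital[1], 99 + e$cfg$buyer_endowment)
  expect_equal(e$capital[37], 0)                 # absorbed into the buyer
  expect_equal(length(members_of <- which(e$org == 1L & !e$patron)), 5)
  expect_equal(sum(e$org == 2L), 5)
  # co-op members carry drawn initial loyalty; PC recruits start at 0
  expect_true(all(e$loyalty[e$org == 2L] >= 0))
  expect_true(all(e$loyalty[members_of] == 0))
  # 6 fishers committed on the buyer side, 5 on the co-op side
  expect_equal(sum(e$org > 0L), 11)
})

test_that("capital ties at entry break toward the lowest fisher id", {
  e <- empty_pool_state()
  e$capital[c(41, 17)] <- 77
  annual_entry(e, year = 0)
  expect_equal(e$o_patron[1], 17L)
})

test_that("entry is skipped when too few fishers are inactive", {
  e <- empty_pool_state()
  e$org[1:97] <- 99L       # only 3 inactive fishers remain
  n_orgs <- length(e$o_kind)
  annual_entry(e, year = 2)
  expect_equal(length(e$o_kind), n_orgs)   # neither entry happened
  ev <- do.call(rbind, e$events)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev[, 4] == 3))           # both logged as skipped
})

test_that("crew selection recruits the best-known inactive fisher", {
  e <- empty_pool_state()
  # one under-supplied buyer that knows exactly two inactive fishers
  e$o_kind <- 1L; e$o_alive <- TRUE; e$o_capital <- 100
  e$o_entry_year <- 0L; e$o_patron <- 0L
  e$o_known <- list(c(5L, 6L))
  e$rel[5] <- 0.9; e$rel[6] <- 0.1
  e$skl[5] <- 1.5; e$skl[6] <- 1.5   # one recruit satisfies the demand
  select_crews(e)
  expect_equal(e$org[5], 1L)         # highest reputation wins
  expect_equal(e$org[6], 0L)
  expect_equal(e$loyalty[5], 0)      # no loyalty with a new buyer
})

test_that("satisfied buyers recruit nobody; empty pools change nothing", {
  e <- empty_pool_state()
  e$o_kind <- 1L; e$o_alive <- TRUE; e$o_capital <- 100
  e$o_entry_year <- 0L; e$o_patron <- 0L
  e$o_known <- list(1:100)
  e$org[1] <- 1L; e$skl[1] <- 2      # expected delivery 1.6 >= share 1
  before <- e$org
  select_crews(e)
  expect_identical(e$org, before)
  # under-supplied but no inactive fishers left
  e$skl[1] <- 0.1
  e$org[] <- 99L; e$org[1] <- 1L
  before <- e$org
  select_crews(e)
  expect_identical(e$org, before)
})

test_that("contract renewal dismisses the least loyal members first", {
  e <- empty_pool_state()
  e$o_kind <- 1L; e$o_alive <- TRUE; e$o_capital <- 100
  e$o_entry_year <- 0L; e$o_patron <- 0L; e$o_known <- list(integer(0))
  e$org[1:3] <- 1L
  e$loyalty[1:3] <- c(5, 1, 3)
  e$delivered <- 6                   # avg 2 vs market share 1: over-supplied
  renew_contracts(e, 1L)
  expect_equal(e$org[2], 0L)         # loyalty 1 went first
  expect_equal(e$org[3], 0L)         # then loyalty 3
  expect_equal(e$org[1], 1L)         # projected 2 <= 1 + 2: kept
  expect_equal(e$loyalty[2], 0)      # relationship-scoped loyalty reset
  # an under-supplied buyer dismisses nobody
  e2 <- empty_pool_state()
  e2$o_kind <- 1L; e2$o_alive <- TRUE; e2$o_capital <- 100
  e2$o_entry_year <- 0L; e2$o_patron <- 0L; e2$o_known <- list(integer(0))
  e2$org[1:3] <- 1L
  e2$delivered <- 0.5
  renew_contracts(e2, 1L)
  expect_equal(sum(e2$org == 1L), 3)
})

test_that("co-op expulsion removes exactly the loyalty-exhausted members", {
  e <- empty_pool_state()
  e$o_kind <- 2L; e$o_alive <- TRUE; e$o_capital <- 0
  e$o_entry_year <- 0L; e$o_patron <- 0L; e$o_known <- list(integer(0))
  e$org[1:4] <- 1L
  e$loyalty[1:4] <- c(3, 0, 1, 0)
  expel_member(e, 1L)
  expect_equal(which(e$org == 1L), c(1L, 3L))
  e$loyalty[c(1, 3)] <- c(2, 2)
  expel_member(e, 1L)
  expect_equal(which(e$org == 1L), c(1L, 3L))   # all positive: no change
})

test_that("dissolution applies the form rules and the reason precedence", {
  mk <- function() {
    e <- empty_pool_state()
    e$o_kind <- c(1L, 2L, 2L, 2L)
    e$o_alive <- rep(TRUE, 4)
    e$o_capital <- c(100, 0, 0, 0)
    e$o_entry_year <- c(0L, 0L, 1L, 2L)
    e$o_patron <- rep(0L, 4)
    e$o_known <- list(integer(0), integer(0), integer(0), integer(0))
    e$org[1:2] <- 1L; e$org[3:7] <- 2L; e$org[8] <- 3L; e$org[9:13] <- 4L
    e$loyalty[3:13] <- 5
    e
  }
  # buyer: any negative capital dissolves, members become inactive
  e <- mk(); e$o_capital[1] <- -0.01
  dissolution_check(e, year = 3)
  expect_false(e$o_alive[1])
  expect_true(all(e$org[1:2] == 0L))
  ev <- do.call(rbind, e$events)
  expect_equal(ev[1, 5], 1)          # reason: capital
  expect_equal(ev[1, 6], 3)          # age in whole years

  # co-op below minimum size dissolves with reason "members"
  e <- mk()
  dissolution_check(e, year = 3)
  expect_false(e$o_alive[3])         # the single-member co-op
  ev <- do.call(rbind, e$events)
  expect_equal(ev[ev[, 2] == 3, 5], 3)

  # co-op loyalty exhausted dissolves with reason "loyalty"
  e <- mk(); e$loyalty[9:13] <- 0
  dissolution_check(e, year = 5)
  ev <- do.call(rbind, e$events)
  expect_equal(ev[ev[, 2] == 4, 5], 2)

  # co-op capital is the members' aggregate: pot + member capital; and
  # capital takes precedence over loyalty when both conditions hold
  e <- mk(); e$o_capital[4] <- -10    # members still hold 5 x 20
  dissolution_check(e, year = 3)
  expect_true(e$o_alive[4])
  e <- mk(); e$o_capital[4] <- -10; e$capital[9:13] <- 0; e$loyalty[9:13] <- 0
  dissolution_check(e, year = 3)
  expect_false(e$o_alive[4])
  ev <- do.call(rbind, e$events)
  expect_equal(ev[ev[, 2] == 4, 5], 1)   # capital, not loyalty

  # a dissolving co-op's positive pot is liquidated evenly to the members
  e <- mk(); e$o_capital[4] <- 50; e$org[9:12] <- 0L  # 1 member left
  dissolution_check(e, year = 3)       # below min size
  expect_false(e$o_alive[4])
  expect_equal(e$capital[13], 70)
  # and evenly when several members remain (loyalty-exhausted co-op)
  e <- mk(); e$o_capital[4] <- 50; e$loyalty[9:13] <- 0
  dissolution_check(e, year = 3)
  expect_false(e$o_alive[4])
  expect_equal(e$capital[9:13], rep(30, 5))

  # a dissolved buyer's founder returns to the pool
  e <- mk(); e$o_patron[1] <- 2L; e$patron[2] <- TRUE; e$o_capital[1] <- -1
  dissolution_check(e, year = 3)
  expect_false(e$patron[2])
  expect_equal(e$org[2], 0L)
})
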