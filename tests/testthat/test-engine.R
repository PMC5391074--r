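test_that("the C++ and R engines are bit-identical from the same seed", {
  for (preset in c("full_model", "full_model_stochastic",
                   "full_model_seasonal", "reference",
                   "entry_cheating_equal_rates")) {
    cfg <- smili_preset(preset, years = 2)
    a <- run_simulation(cfg, seed = 11, engine = "cpp")
    b <- run_simulation(cfg, seed = 11, engine = "r")
    expect_identical(a$daily, b$daily, label = paste(preset, "daily"))
    expect_identical(a$orgs, b$orgs, label = paste(preset, "orgs"))
    expect_identical(a$events, b$events, label = paste(preset, "events"))
  }
  # the as-printed cheat-rule variant runs through the same machinery
  cfg <- smili_preset("full_model", years = 1,
                      cheat_rule_variant = "as_printed")
  a <- run_simulation(cfg, seed = 3, engine = "cpp")
  b <- run_simulation(cfg, seed = 3, engine = "r")
  expect_identical(a$daily, b$daily)
})

test_that("runs are reproducible and seeds actually matter", {
  cfg <- smili_preset("full_model", years = 2)
  a <- run_simulation(cfg, seed = 5)
  b <- run_simulation(cfg, seed = 5)
  expect_identical(a$daily, b$daily)
  expect_identical(a$events, b$events)
  c2 <- run_simulation(cfg, seed = 6)
  expect_false(identical(a$daily, c2$daily))
})

test_that("fisher conservation holds on every day", {
  sim <- run_simulation(smili_preset("full_model", years = 3), seed = 2)
  d <- sim$daily
  expect_true(all(d$pc_members + d$coop_members + d$patrons + d$inactive ==
                    sim$config$n_fishers))
  # in the reference scenario there are no patrons, so the three-way
  # identity of active forms plus inactive holds exactly
  simr <- run_simulation(smili_preset("reference", years = 2), seed = 2)
  dr <- simr$daily
  expect_true(all(dr$patrons == 0))
  expect_true(all(dr$pc_members + dr$coop_members + dr$inactive == 100))
})

test_that("the daily currency ledger balances exactly", {
  cfg <- smili_preset("full_model", years = 1)
  sim <- run_simulation(cfg, seed = 4)
  d <- sim$daily
  total <- d$fisher_capital + d$org_capital
  base <- cfg$n_fishers * cfg$initial_capital
  delta <- diff(c(base, total))
  # money enters only from fish sales and entry endowments, leaves only as
  # sunk daily fishing costs and dissolution write-offs
  expect_lt(max(abs(delta - (d$money_in - d$money_out - d$write_off))), 1e-8)
})

test_that("biomass stays within physical bounds and harvests conserve", {
  sim <- run_simulation(smili_preset("full_model", years = 3), seed = 8)
  expect_true(all(sim$daily$biomass >= 0))
  expect_true(all(sim$daily$harvest >= 0))
  # seasonal capacity peaks at (1 + a) K
  sims <- run_simulation(smili_preset("full_model_seasonal", years = 3),
                         seed = 8)
  amp <- sims$config$seasonal_amplitude
  expect_true(all(sims$daily$biomass <= (1 + amp) * sims$config$K * 1.01))
})

test_that("stepping one day keeps the state consistent", {
  set.seed(10)
  e <- init_state(smili_preset("full_model", years = 1))
  for (i in 1:30) {
    step_day(e)
    expect_equal(sum(e$org > 0) + sum(e$org == 0L), e$cfg$n_fishers)
    expect_true(all(e$loyalty >= 0))
    expect_gte(e$N, 0)
    # affiliation is exclusive and only to living organizations
    live <- which(e$o_alive)
    expect_true(all(e$org[e$org > 0L] %in% live))
  }
  expect_equal(e$day, 30L)
})

test_that("co-op membership stabilizes while PC membership fluctuates", {
  # single-run dynamics at homogeneous traits and low initial loyalty:
  # co-ops that establish keep fixed membership, buyers churn crews
  cfg <- smili_preset("full_model", years = 40,
                      reliability_sd = 0, skills_sd = 0,
                      initial_loyalty_mean = 5)
  sim <- run_simulation(cfg, seed = 1)
  w <- sim$daily[sim$daily$year >= 10 & sim$daily$year < 40, ]
  expect_gt(var(w$pc_members), var(w$coop_members))
})

test_that("summaries compute the window statistics they promise", {
  sim <- run_simulation(smili_preset("reference", years = 3), seed = 1)
  ms <- membership_summary(sim, window_years = 1)
  expect_equal(ms$pc + ms$coop + ms$inactive, 100)
  expect_error(membership_summary(sim, window_years = 10), "window")
  # window equal to the whole run is the boundary case
  msall <- membership_summary(sim, window_years = 3)
  expect_equal(msall$pc, mean(sim$daily$pc_members))
  # share arithmetic
  fake <- sim
  fake$daily$pc_members[] <- 20
  fake$daily$coop_members[] <- 30
  expect_equal(membership_summary(fake, 1)$coop_share_pct, 60)

  # persistence: ages {1, 1, 4} average to 2
  fk <- sim
  fk$events <- data.frame(year = c(2, 3, 6), org_id = 1:3, kind = "coop",
                          event = "dissolution", reason = "capital",
                          age = c(1, 1, 4), founder = NA)
  ps <- persistence_summary(fk)
  expect_equal(ps$dissolved$mean_age, 2)
  expect_equal(ps$dissolved$n, 3)

  # homogeneous traits: both forms report reliability exactly 1
  sr <- surviving_reliability(sim, window_years = 1)
  expect_equal(unname(sr), c(1, 1))
  # a form with no active fishers in the window reports NA, not 0
  fake$daily$mean_rel_coop[] <- NaN
  expect_true(is.na(surviving_reliability(fake, 1)[["coop"]]))

  # the cumulative dissolution ledger never decreases
  sim2 <- run_simulation(smili_preset("full_model", years = 5), seed = 3)
  led <- dissolution_ledger(sim2)
  expect_true(nrow(led) > 0)
  for (g in split(led, paste(led$kind, led$reason)))
    expect_true(all(diff(g$cumulative) >= 0))
})
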