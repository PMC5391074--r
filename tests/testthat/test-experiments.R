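test_that("calibration solves the MSY and break-even conditions in closed form", {
  cal <- calibrate()
  expect_equal(cal$q, 0.04 / (2 * 50 * 0.5))     # 8e-4
  expect_equal(cal$fishing_cost, 2)              # p q s K/2
  expect_equal(cal$market_share, 1)              # MSY split over 10 orgs
  expect_equal(cal$msy, 10)
  expect_equal(cal$N_star, 500)
  # the break-even identity: a mean fisher's landing value equals the cost
  expect_equal(cal$price * cal$catch_star, cal$fishing_cost)
  # and a buyer nets exactly zero on it: margin + capped repayment - loan
  phi <- 0.7
  beach <- phi * cal$price * cal$catch_star
  expect_equal((1 - phi) * cal$price * cal$catch_star +
                 min(cal$fishing_cost, beach) - cal$fishing_cost, 0)
  expect_error(calibrate(n_sustainable = 0), "positive")
  # defaults of smili_config are the calibrated values
  cfg <- smili_config()
  expect_equal(cfg$q, cal$q)
  expect_equal(cfg$fishing_cost, cal$fishing_cost)
  expect_equal(cfg$market_share, cal$market_share)
})

test_that("the calibrated reference equilibrates at half the carrying capacity", {
  sim <- run_simulation(smili_preset("reference", years = 15), seed = 1)
  w <- sim$daily[sim$daily$year >= 10, ]
  expect_equal(mean(w$biomass) / sim$config$K, 0.5, tolerance = 0.05)
  expect_equal(mean(w$pc_members + w$coop_members), 50, tolerance = 0.04)
})

test_that("doubling the fishing cost breaks the calibrated break-even", {
  cfg <- smili_preset("reference", years = 10)
  cfg$fishing_cost <- 2 * cfg$fishing_cost
  sim <- run_simulation(cfg, seed = 1)
  # organizations now run at a loss and go out of business
  expect_gt(sum(sim$events$event == "dissolution"), 0)
})

test_that("replicate runs follow the base_seed + r seeding plan exactly", {
  cfg <- smili_preset("full_model", years = 2)
  rr <- run_replicates(cfg, replicates = 3, base_seed = 100,
                       window_years = 1)
  expect_equal(rr$seed, c(100, 101, 102))
  # each row is reproducible by running that seed directly
  sim <- run_simulation(cfg, seed = 101)
  ms <- membership_summary(sim, 1)
  expect_equal(rr$coop[2], ms$coop)
  # and the whole table reproduces
  rr2 <- run_replicates(cfg, replicates = 3, base_seed = 100,
                        window_years = 1)
  expect_identical(rr, rr2)
})

test_that("experiment grids enumerate deterministically and aggregate with dispersion", {
  sp <- experiment_spec("tiny",
                        grid = list(initial_loyalty_mean = c(0, 40),
                                    reliability_sd = c(0.05, 0.3)),
                        replicates = 2, base_seed = 7,
                        overrides = list(years = 2))
  res <- run_experiment(sp, window_years = 1)
  expect_equal(nrow(res$results), 2 * 2 * 2)     # cells x replicates
  expect_equal(nrow(res$aggregate), 4)
  expect_true(all(c("n", "coop_mean", "coop_sd") %in% names(res$aggregate)))
  expect_true(all(res$aggregate$n == 2))
  res2 <- run_experiment(sp, window_years = 1)
  expect_identical(res$results, res2$results)
  expect_error(experiment_spec("bad", grid = list()), "grid")
})
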