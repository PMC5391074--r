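test_that("cheat rule respects its deterministic limits", {
  # full loyalty: never cheats under either variant (loyindex < beta fails
  # with probability 1 when loyindex = 1)
  a <- runif(200); b <- runif(200)
  expect_false(any(cheat_decision(0.5, 1, a, b)))
  expect_false(any(cheat_decision(0.5, 1, a, b, variant = "as_printed")))
  # fully reliable fishers never cheat under the default rule
  expect_false(any(cheat_decision(1, 0, a, b)))
  # the printed variant makes fully reliable fishers cheat whenever
  # loyindex < beta — the inversion the default rule corrects
  expect_true(any(cheat_decision(1, 0, a, b, variant = "as_printed")))
  expect_error(cheat_decision(0.5, 1.2), "loyindex")
})

test_that("Monte-Carlo cheat frequency matches the closed form", {
  n <- 1e5
  cases <- expand.grid(rel = c(0.2, 0.65, 0.9), idx = c(0, 0.5, 0.9))
  set.seed(7)
  for (k in seq_len(nrow(cases))) {
    rel <- cases$rel[k]; idx <- cases$idx[k]
    for (v in c("low_reliability_cheats", "as_printed")) {
      p <- cheat_probability(rel, idx, v)
      freq <- mean(cheat_decision(rep(rel, n), idx, variant = v))
      expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
  # the default-rule frequency at the calibration means: (1-0.65)*1 = 0.35
  set.seed(8)
  freq <- mean(cheat_decision(rep(0.65, n), 0))
  expect_gt(freq, 0.345)
  expect_lt(freq, 0.355)
})

test_that("loan provision reduces organization capital, overdraft allowed", {
  expect_equal(issue_loans(100, 5, 10)$org_capital, 50)
  expect_equal(issue_loans(100, 0, 10)$org_capital, 100)
  # intra-day overdraft: dissolution is deferred to the end of the day
  expect_equal(issue_loans(30, 5, 10)$org_capital, -20)
})

test_that("trade settlement splits value according to the organization", {
  # honest co-op member, landing worth 20, loan 10, fee 1
  s <- settle_trade("coop", FALSE, catch = 2, price = 10, phi = 0.7,
                    loan = 10, fee = 1, fisher_capital = 0)
  expect_equal(s$fisher, 9)
  expect_equal(s$home, 11)
  expect_equal(s$market_in, 20)
  # co-op members get the full market price (no buyer margin)
  expect_equal(s$fisher + s$home, s$market_in)

  # honest PC: buyer pays the beach price and recovers the loan, capped at
  # the landing's beach value
  s <- settle_trade("pc", FALSE, catch = 2, price = 10, phi = 0.7, loan = 10)
  expect_equal(s$fisher, 14 - 10)      # beach 14 minus full repayment
  expect_equal(s$home, 6 + 10)
  s <- settle_trade("pc", FALSE, catch = 0.5, price = 10, phi = 0.7,
                    loan = 10)
  expect_equal(s$fisher, 0)            # beach 3.5 all goes to repayment
  expect_equal(s$home, 1.5 + 3.5)      # under-repayment: buyer swallows loss
  s <- settle_trade("pc", FALSE, catch = 0, price = 10, phi = 0.7, loan = 10)
  expect_equal(s$home, 0)              # zero landing: nothing recovered

  # cheating: fisher keeps the loan, a random other organization gets the
  # trade margin
  s <- settle_trade("pc", TRUE, catch = 2, price = 10, phi = 0.7, loan = 10)
  expect_equal(s$fisher, 14)
  expect_equal(s$home, 0)
  expect_equal(s$other, 6)
  s <- settle_trade("pc", TRUE, catch = 2, price = 10, phi = 0.7, loan = 10,
                    has_other_org = FALSE)
  expect_equal(s$other, 0)
  expect_equal(s$market_in, 14)        # external market pays the beach price
  s <- settle_trade("coop", TRUE, catch = 0, price = 10, phi = 0.7, loan = 10)
  expect_equal(s$fisher, 0)            # keeps the loan; no fee when cheating

  # capital-sharing contribution above the threshold
  s <- settle_trade("coop", FALSE, catch = 2, price = 10, phi = 0.7,
                    loan = 10, fee = 1, contribution_rate = 0.1,
                    capital_threshold = 5, fisher_capital = 100)
  expect_equal(s$fisher, 9 - 0.1 * 109)
  expect_equal(s$home, 11 + 0.1 * 109)

  # conservation: deltas always sum to the money entering from the market
  for (cheated in c(TRUE, FALSE)) for (kind in c("pc", "coop")) {
    s <- settle_trade(kind, cheated, catch = 1.3, price = 10, phi = 0.7,
                      loan = 2, fee = 0.2, fisher_capital = 3)
    expect_equal(s$fisher + s$home + s$other, s$market_in)
  }
})

test_that("loyalty grows on honest days and erodes faster on cheats", {
  expect_equal(update_loyalty(5, "pc", FALSE, g = 1), 6)
  expect_equal(update_loyalty(5, "coop", FALSE, g = 1), 5.5)
  expect_equal(update_loyalty(0, "pc", TRUE, g = 1), 0)     # floored
  expect_equal(update_loyalty(5, "pc", TRUE, g = 1), 3)     # d = 2g
  expect_equal(update_loyalty(5, "coop", TRUE, g = 1), 4)   # d scaled to form
  # alternating honest/cheat drifts downward for both forms
  for (kind in c("pc", "coop")) {
    l <- 20
    for (i in 1:10) l <- update_loyalty(update_loyalty(l, kind, FALSE, g = 1),
                                        kind, TRUE, g = 1)
    expect_lt(l, 20)
  }
})
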