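#' Cheating decision and its closed-form probability
#'
#' Each trading day a fisher decides whether to divert the catch to another
#' organization while keeping the loan.  Two i.i.d. uniform thresholds
#' `alpha` and `beta` are drawn per decision and compared against the
#' fisher's fixed reliability and current loyalty index.
#'
#' Under the default `"low_reliability_cheats"` variant a fisher cheats iff
#' `reliability < alpha` and `loyindex < beta`, so
#' \deqn{P(\mathrm{cheat}) = (1 - \mathrm{reliability})(1 - \mathrm{loyindex}):}
#' unreliable, unattached fishers cheat most, and fully reliable or fully
#' loyal fishers never do.  The `"as_printed"` variant uses
#' `reliability > alpha` instead (P = reliability * (1 - loyindex)) and is
#' retained for auditing the consequences of that rule.
#'
#' @param reliability Fixed reliability in \[0, 1\] (vectorized).
#' @param loyindex Loyalty index in \[0, 1\] (see [loyalty_index()]).
#' @param alpha,beta Uniform(0,1) draws; drawn internally when `NULL`.
#' @param variant Rule variant.
#' @return `cheat_decision()`: logical vector; `cheat_probability()`: the
#'   exact per-decision probability.
#' @export
#' @examples
#' cheat_probability(0.65, 0)                 # 0.35
#' cheat_probability(1, 0.2)                  # 0: reliable fishers never cheat
cheat_decision <- function(reliability, loyindex, alpha = NULL, beta = NULL,
                           variant = c("low_reliability_cheats", "as_printed")) {
  variant <- match.arg(variant)
  if (any(loyindex < 0 | loyindex > 1))
    stop("loyindex must lie in [0, 1]", call. = FALSE)
  k <- max(length(reliability), length(loyindex))
  if (is.null(alpha)) alpha <- stats::runif(k)
  if (is.null(beta)) beta <- stats::runif(k)
  rel_gate <- if (variant == "low_reliability_cheats") reliability < alpha
              else reliability > alpha
  rel_gate & (loyindex < beta)
}

#' @rdname cheat_decision
#' @export
cheat_probability <- function(reliability, loyindex,
                              variant = c("low_reliability_cheats",
                                          "as_printed")) {
  variant <- match.arg(variant)
  p_rel <- if (variant == "low_reliability_cheats") 1 - reliability
           else reliability
  p_rel * (1 - loyindex)
}

#' Morning loan provision
#'
#' Every borrowing member receives the day's fishing cost from its
#' organization; the organization's capital is reduced accordingly and may go
#' negative intra-day (dissolution is only checked at the end of the day,
#' which is how buyers get trapped lending to unproductive crews).
#'
#' @param org_capital Organization capital before lending.
#' @param n_members Number of borrowing members.
#' @param fishing_cost Daily trip cost per fisher.
#' @return List with `org_capital` (after lending) and `total_lent`.
#' @export
#' @examples
#' issue_loans(30, 5, 10)   # capital -20: overdraft allowed until day end
issue_loans <- function(org_capital, n_members, fishing_cost) {
  total <- n_members * fishing_cost
  list(org_capital = org_capital - total, total_lent = total)
}

#' Settle one fisher's trade
#'
#' Computes the capital deltas of landing and selling one fisher's catch.
#' Honest PC fishers land with their buyer: the buyer sells at the market
#' price `p`, pays the fisher the beach price `phi * p`, and recovers the
#' loan capped at the beach value of the landing (poor catches under-repay).
#' Honest co-op members get the full market price, repay the loan capped at
#' the landing value, pay the daily membership fee into the pot, and
#' contribute a small fraction of personal capital when above the threshold.
#' A cheating fisher keeps the loan and sells at the beach price to a random
#' other organization, which books the trade margin; with no other
#' organization in existence the catch goes to the external market.
#'
#' @param kind `"pc"` or `"coop"` (the fisher's home organization).
#' @param cheated Logical.
#' @param catch Landed biomass.
#' @param price Market price per unit biomass.
#' @param phi Beach price fraction.
#' @param loan Loan owed (the daily fishing cost).
#' @param fee Co-op daily membership fee.
#' @param contribution_rate,capital_threshold Co-op capital-sharing rule.
#' @param fisher_capital The fisher's personal capital before settlement.
#' @param has_other_org Is there at least one other living organization a
#'   cheater could sell to?
#' @return List of deltas: `fisher`, `home`, `other` and `market_in` (money
#'   entering the community from the market).
#' @export
#' @examples
#' # honest co-op member, landing worth 20, loan 10, fee 1:
#' settle_trade("coop", FALSE, catch = 2, price = 10, phi = 0.7, loan = 10,
#'              fee = 1, fisher_capital = 0)
settle_trade <- function(kind, cheated, catch, price, phi, loan, fee = 0,
                         contribution_rate = 0, capital_threshold = Inf,
                         fisher_capital = 0, has_other_org = TRUE) {
  value <- price * catch
  if (cheated) {
    beach <- phi * value
    return(list(fisher = beach,
                home = 0,
                other = if (has_other_org) (1 - phi) * value else 0,
                market_in = if (has_other_org) value else beach))
  }
  if (kind == "pc") {
    beach <- phi * value
    repay <- min(loan, beach)
    list(fisher = beach - repay,
         home = (1 - phi) * value + repay,
         other = 0, market_in = value)
  } else {
    repay <- min(loan, value)
    d_fisher <- value - repay - fee
    d_home <- repay + fee
    new_cap <- fisher_capital + d_fisher
    if (new_cap > capital_threshold) {
      contrib <- contribution_rate * new_cap
      d_fisher <- d_fisher - contrib
      d_home <- d_home + contrib
    }
    list(fisher = d_fisher, home = d_home, other = 0, market_in = value)
  }
}

#' Loyalty update after a trading day
#'
#' Honest interactions build loyalty at the organization's growth rate (the
#' full PC rate, or the co-op fraction of it, reflecting the higher
#' transaction costs of collective arrangements); a cheating day erodes it,
#' floored at zero.  The decay scales with the form's own growth rate
#' (`d` for a PC, `d * coop_rate_fraction` for a co-op, default `d = 2g`):
#' both forms lose loyalty at the same multiple of the rate they build it, so
#' erosion outpaces growth equally and the halved co-op rate means co-op
#' loyalty simply evolves at half speed.
#'
#' @param loyalty Current loyalty (>= 0, vectorized).
#' @param kind `"pc"` or `"coop"`.
#' @param cheated Logical (vectorized).
#' @param g PC loyalty growth per honest day.
#' @param coop_rate_fraction Co-op rates as a fraction of the PC rates.
#' @param d PC loyalty decay per cheating day.
#' @return Updated loyalty.
#' @export
#' @examples
#' update_loyalty(0, "coop", FALSE, g = 1)   # 0.5
#' update_loyalty(1, "pc", TRUE, g = 1)      # 0 (floored)
update_loyalty <- function(loyalty, kind, cheated, g, coop_rate_fraction = 0.5,
                           d = 2 * g) {
  stopifnot(g > 0, d >= 0)
  frac <- if (kind == "coop") coop_rate_fraction else 1
  ifelse(cheated, pmax(0, loyalty - d * frac), loyalty + g * frac)
}
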