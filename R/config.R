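#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set for one fishery simulation:
#' the fisher population, the fish stock and its environmental regime, the
#' daily economics of lending and trading, the loyalty dynamics, and the
#' annual entry rules.  Defaults are the calibrated values returned by
#' [calibrate()] combined with the full-model behavioural settings; use
#' [smili_preset()] for the named scenario presets.
#'
#' @param n_fishers Number of fishers in the community (fixed pool, no
#'   demographic turnover).
#' @param reliability_mean,reliability_sd Normal distribution of the fixed
#'   reliability trait; draws are clipped to \[0, 1\].
#' @param skills_mean,skills_sd Normal distribution of fixed fishing skills;
#'   draws are clipped at 0.
#' @param initial_loyalty_mean,initial_loyalty_sd Normal distribution of the
#'   starting loyalty of co-op members (a proxy for their history of working
#'   together); draws are clipped at 0.  Fishers joining a buyer always start
#'   at loyalty 0.
#' @param initial_capital Starting personal capital of every fisher
#'   (currency units).
#' @param loyalty_half_saturation Half-saturation constant \eqn{h} of the
#'   loyalty index \eqn{l / (l + h)}; loyalty \eqn{h} maps to index 0.5.
#' @param K Carrying capacity of the fish stock (biomass units).
#' @param r Intrinsic (logistic) growth rate per day.
#' @param q Catchability per unit skill per day: an active fisher of skill
#'   \eqn{s} catches \eqn{q s N} biomass from a stock of size \eqn{N}.
#' @param N0 Initial stock biomass.
#' @param regime Environmental regime: `"deterministic"` (no forcing),
#'   `"stochastic"` (unit-mean lognormal daily multiplier on catch rates) or
#'   `"seasonal"` (sinusoidal modulation of the carrying capacity).
#' @param stochastic_cv Coefficient of variation of the daily catch
#'   multiplier in the stochastic regime.
#' @param seasonal_amplitude Relative amplitude (in \[0, 1)) of the seasonal
#'   carrying-capacity cycle.
#' @param price Fixed market price per unit biomass.
#' @param fishing_cost Cost of one fisher's daily trip, lent by the
#'   organization each morning.
#' @param beach_price_fraction Fraction \eqn{\phi} of the market price a buyer
#'   pays its fishers (the buyer margin is \eqn{1 - \phi}); also the price a
#'   cheating fisher gets when diverting catch elsewhere.
#' @param loyalty_growth Loyalty gained per honest trading day in a
#'   patron-client relationship (co-op members gain
#'   `loyalty_growth * coop_rate_fraction`).
#' @param coop_rate_fraction Co-op loyalty growth as a fraction of the PC
#'   rate (0.5 encodes the higher transaction costs of collective action).
#' @param loyalty_decay Loyalty lost on a cheating day (floored at 0);
#'   default twice the PC growth rate so decay outpaces growth.
#' @param membership_fee Daily fee an honest co-op member pays into the pot.
#' @param contribution_rate Fraction of personal capital a co-op member
#'   transfers to the pot on days their capital exceeds `capital_threshold`.
#' @param capital_threshold Personal-capital threshold for the contribution.
#' @param min_size Minimum viable co-op size; smaller co-ops dissolve.
#' @param known_fraction Fraction of the population whose reputation a buyer
#'   knows (the fixed subset is drawn at the buyer's creation).
#' @param cheat_rule_variant `"low_reliability_cheats"` (default): a fisher
#'   cheats iff `reliability < alpha` and `loyindex < beta` with alpha, beta
#'   i.i.d. uniform, so P(cheat) = (1-reliability)(1-loyindex).
#'   `"as_printed"` uses the inequality `reliability > alpha` instead, giving
#'   P(cheat) = reliability (1-loyindex); retained for auditability.
#' @param cheating_enabled Logical; if `FALSE` no cheating decisions are made.
#' @param entry_enabled Logical; if `TRUE` one new buyer and one new co-op
#'   attempt to enter on the first day of every year.
#' @param buyer_endowment Capital a new buyer receives on top of its
#'   founder's personal capital.
#' @param entry_members Number of fishers recruited by each entering
#'   organization (also the size of the initial organizations).
#' @param market_share Fixed daily fish demand of every organization
#'   (biomass/day), granted at entry.
#' @param n_init_buyers,n_init_coops Organizations present at day 0 (used by
#'   the reference preset; entry-driven scenarios start from zero).
#' @param years Simulated horizon in years of 365 days.
#'
#' @return A list of class `smili_config`.
#' @seealso [smili_preset()], [calibrate()], [run_simulation()]
#' @export
#' @examples
#' cfg <- smili_config(years = 5)
#' cfg$fishing_cost          # calibrated so income = expenses at MSY
smili_config <- function(n_fishers = 100L,
                         reliability_mean = 0.65,
                         reliability_sd = 0.3,
                         skills_mean = 0.5,
                         skills_sd = 0.3,
                         initial_loyalty_mean = 40,
                         initial_loyalty_sd = 5,
                         initial_capital = 20,
                         loyalty_half_saturation = 40,
                         K = 1000,
                         r = 0.04,
                         q = NULL,
                         N0 = NULL,
                         regime = c("deterministic", "stochastic", "seasonal"),
                         stochastic_cv = 0.3,
                         seasonal_amplitude = 0.5,
                         price = 10,
                         fishing_cost = NULL,
                         beach_price_fraction = 0.7,
                         loyalty_growth = 1,
                         coop_rate_fraction = 0.5,
                         loyalty_decay = NULL,
                         membership_fee = NULL,
                         contribution_rate = 5e-6,
                         capital_threshold = NULL,
                         min_size = 2L,
                         known_fraction = 0.5,
                         cheat_rule_variant = c("low_reliability_cheats",
                                                "as_printed"),
                         cheating_enabled = TRUE,
                         entry_enabled = TRUE,
                         buyer_endowment = NULL,
                         entry_members = 5L,
                         market_share = NULL,
                         n_init_buyers = 0L,
                         n_init_coops = 0L,
                         years = 100L) {
  regime <- match.arg(regime)
  cheat_rule_variant <- match.arg(cheat_rule_variant)

  # fill economic/ecological gaps from the calibration closed form
  cal <- calibrate(n_sustainable = 50L, K = K, r = r, price = price,
                   skills_mean = skills_mean)
  if (is.null(q)) q <- cal$q
  if (is.null(fishing_cost)) fishing_cost <- price * q * skills_mean * K / 2
  if (is.null(market_share)) market_share <- cal$market_share
  if (is.null(N0)) N0 <- K
  if (is.null(loyalty_decay)) loyalty_decay <- 2 * loyalty_growth
  if (is.null(membership_fee)) membership_fee <- 0.1 * fishing_cost
  if (is.null(capital_threshold)) capital_threshold <- 10 * initial_capital
  if (is.null(buyer_endowment)) buyer_endowment <- entry_members * initial_capital

  cfg <- list(
    n_fishers = as.integer(n_fishers),
    reliability_mean = reliability_mean, reliability_sd = reliability_sd,
    skills_mean = skills_mean, skills_sd = skills_sd,
    initial_loyalty_mean = initial_loyalty_mean,
    initial_loyalty_sd = initial_loyalty_sd,
    initial_capital = initial_capital,
    loyalty_half_saturation = loyalty_half_saturation,
    K = K, r = r, q = q, N0 = N0,
    regime = regime, stochastic_cv = stochastic_cv,
    seasonal_amplitude = seasonal_amplitude,
    price = price, fishing_cost = fishing_cost,
    beach_price_fraction = beach_price_fraction,
    loyalty_growth = loyalty_growth,
    coop_rate_fraction = coop_rate_fraction,
    loyalty_decay = loyalty_decay,
    membership_fee = membership_fee,
    contribution_rate = contribution_rate,
    capital_threshold = capital_threshold,
    min_size = as.integer(min_size),
    known_fraction = known_fraction,
    cheat_rule_variant = cheat_rule_variant,
    cheating_enabled = isTRUE(cheating_enabled),
    entry_enabled = isTRUE(entry_enabled),
    buyer_endowment = buyer_endowment,
    entry_members = as.integer(entry_members),
    market_share = market_share,
    n_init_buyers = as.integer(n_init_buyers),
    n_init_coops = as.integer(n_init_coops),
    years = as.integer(years)
  )
  class(cfg) <- "smili_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "smili_config"))
  with(cfg, {
    if (n_fishers <= 0L) stop("n_fishers must be positive", call. = FALSE)
    if (reliability_sd < 0 || skills_sd < 0 || initial_loyalty_sd < 0)
      stop("standard deviations must be >= 0", call. = FALSE)
    if (loyalty_half_saturation <= 0)
      stop("loyalty_half_saturation must be > 0", call. = FALSE)
    if (K <= 0 || r < 0 || q < 0) stop("need K > 0, r >= 0, q >= 0",
                                       call. = FALSE)
    if (seasonal_amplitude < 0 || seasonal_amplitude >= 1)
      stop("seasonal_amplitude must lie in [0, 1)", call. = FALSE)
    if (stochastic_cv < 0) stop("stochastic_cv must be >= 0", call. = FALSE)
    if (beach_price_fraction <= 0 || beach_price_fraction > 1)
      stop("beach_price_fraction must lie in (0, 1]", call. = FALSE)
    if (loyalty_decay < 0) stop("loyalty_decay must be >= 0", call. = FALSE)
    if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
    if (known_fraction < 0 || known_fraction > 1)
      stop("known_fraction must lie in [0, 1]", call. = FALSE)
    if (years < 1L) stop("years must be >= 1", call. = FALSE)
    if (entry_members < 1L) stop("entry_members must be >= 1", call. = FALSE)
  })
  invisible(cfg)
}

#' Scenario presets
#'
#' Named parameter sets spanning the validation ladder and the production
#' experiments:
#' \describe{
#'   \item{`reference`}{The calibrated baseline: 5 buyers and 5 co-ops with 5
#'     identical fishers each (reliability 1, skills 0.5), equal loyalty
#'     growth rates, no cheating, no entry.  The fishery sustains 50 active
#'     fishers at maximum sustainable yield.}
#'   \item{`entry_no_cheating`}{Annual entry switched on, starting from an
#'     empty fishery; still no cheating, equal loyalty rates, homogeneous
#'     fishers.}
#'   \item{`entry_cheating_equal_rates`}{As above with cheating enabled.}
#'   \item{`full_model`}{Cheating, annual entry, co-op loyalty growth at half
#'     the PC rate, heterogeneous reliability N(0.65, 0.3) and skills
#'     N(0.5, 0.3), co-op initial loyalty N(40, 5).}
#'   \item{`full_model_stochastic`, `full_model_seasonal`}{The full model
#'     under the stochastic or seasonal environmental regime.}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides passed to [smili_config()] (e.g. `years`,
#'   `initial_loyalty_mean`).
#' @return A `smili_config`.
#' @export
#' @examples
#' smili_preset("reference", years = 10)
smili_preset <- function(name = c("reference", "entry_no_cheating",
                                  "entry_cheating_equal_rates", "full_model",
                                  "full_model_stochastic",
                                  "full_model_seasonal"),
                         ...) {
  name <- match.arg(name)
  homog <- list(reliability_mean = 1.0, reliability_sd = 0,
                skills_mean = 0.5, skills_sd = 0,
                initial_loyalty_mean = 0, initial_loyalty_sd = 0)
  base <- switch(name,
    reference = c(homog, list(cheating_enabled = FALSE, entry_enabled = FALSE,
                              coop_rate_fraction = 1,
                              n_init_buyers = 5L, n_init_coops = 5L)),
    entry_no_cheating = c(homog, list(cheating_enabled = FALSE,
                                      entry_enabled = TRUE,
                                      coop_rate_fraction = 1)),
    entry_cheating_equal_rates = c(homog, list(cheating_enabled = TRUE,
                                               entry_enabled = TRUE,
                                               coop_rate_fraction = 1)),
    full_model = list(),
    full_model_stochastic = list(regime = "stochastic"),
    full_model_seasonal = list(regime = "seasonal")
  )
  over <- list(...)
  args <- utils::modifyList(base, over)
  cfg <- do.call(smili_config, args)
  attr(cfg, "preset") <- name
  cfg
}

#' Calibrate the bioeconomic parameters
#'
#' Solves, in closed form, for the catchability, daily fishing cost and
#' per-organization market share such that (i) a community of
#' `n_sustainable` active fishers of mean skill drives the stock to its
#' maximum-sustainable-yield equilibrium \eqn{N^* = K/2}, and (ii) at that
#' equilibrium every organization's daily income exactly equals its daily
#' expenses (break-even).
#'
#' With total effort \eqn{E = n \cdot \bar s} skill units, the harvested
#' logistic equilibrium is \eqn{N^* = K (1 - qE/r)}; setting \eqn{N^* = K/2}
#' gives \eqn{q = r / (2E)}, and the total equilibrium harvest equals the MSY
#' \eqn{rK/4}.  Break-even requires the value of a mean fisher's daily
#' landing to equal the trip cost, \eqn{c = p\, q\, \bar s\, K/2}: the buyer
#' then nets \eqn{(1-\phi) p Y + \min(c, \phi p Y) - c = 0} per fisher (the
#' loan repayment is capped at the beach value of the landing), and a co-op's
#' pot nets only the membership fee, an internal member-to-pot transfer.
#' The market share splits the MSY evenly over the ten reference
#' organizations, so demand equals sustainable supply.
#'
#' @param n_sustainable Number of active fishers the fishery must sustain.
#' @param K,r Stock parameters (carrying capacity; daily logistic rate).
#' @param price Market price per unit biomass.
#' @param skills_mean Mean fishing skill.
#' @param n_orgs Number of organizations sharing the market at calibration.
#' @return A list with elements `q`, `fishing_cost`, `market_share`, `price`,
#'   `msy`, `N_star` and `catch_star` (per-mean-fisher equilibrium catch).
#' @export
#' @examples
#' calibrate()           # q = 8e-4, cost = 2, market share = 1 at defaults
calibrate <- function(n_sustainable = 50L, K = 1000, r = 0.04, price = 10,
                      skills_mean = 0.5, n_orgs = 10L) {
  if (n_sustainable <= 0 || skills_mean <= 0 || r <= 0 || K <= 0)
    stop("calibration requires positive n_sustainable, skills_mean, r, K",
         call. = FALSE)
  effort <- n_sustainable * skills_mean
  q <- r / (2 * effort)
  N_star <- K / 2
  catch_star <- q * skills_mean * N_star
  list(q = q,
       fishing_cost = price * catch_star,
       market_share = (r * K / 4) / n_orgs,
       price = price,
       msy = r * K / 4,
       N_star = N_star,
       catch_star = catch_star)
}

#' @export
print.smili_config <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("<smili_config>",
      if (!is.null(preset)) paste0(" preset: ", preset), "\n", sep = "")
  cat(sprintf("  fishers: %d | reliability N(%.2f, %.2f) | skills N(%.2f, %.2f)\n",
              x$n_fishers, x$reliability_mean, x$reliability_sd,
              x$skills_mean, x$skills_sd))
  cat(sprintf("  stock: K = %g, r = %g/day, q = %g | regime: %s | N0 = %g\n",
              x$K, x$r, x$q, x$regime, x$N0))
  cat(sprintf("  economics: price %g, trip cost %g, beach fraction %g, share %g\n",
              x$price, x$fishing_cost, x$beach_price_fraction, x$market_share))
  cat(sprintf("  loyalty: growth %g (co-op x%g), decay %g, half-sat %g, coop init N(%g, %g)\n",
              x$loyalty_growth, x$coop_rate_fraction, x$loyalty_decay,
              x$loyalty_half_saturation, x$initial_loyalty_mean,
              x$initial_loyalty_sd))
  cat(sprintf("  cheating: %s (%s) | entry: %s | %d years\n",
              if (x$cheating_enabled) "on" else "off", x$cheat_rule_variant,
              if (x$entry_enabled) "annual" else "off", x$years))
  invisible(x)
}
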