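#' Sample a fisher population
#'
#' Draws the fixed traits of the fisher community.  Reliability is drawn from
#' a normal distribution and clipped to \[0, 1\]; fishing skills are drawn
#' from a normal distribution and clipped at 0 (clipping, not resampling,
#' preserves the ordering of means across experiment grids).  All fishers
#' start unaffiliated ("inactive"), with loyalty 0 and the configured
#' starting capital.
#'
#' @param cfg A [smili_config()] (only the population fields are used).
#' @return A data frame with one row per fisher: `id`, `reliability`,
#'   `skills` (fixed traits), `loyalty`, `capital`, `affiliation`
#'   (`0` = inactive).
#' @export
#' @examples
#' set.seed(1)
#' pop <- sample_population(smili_config())
#' nrow(pop)                     # 100
#' range(pop$reliability)        # within [0, 1]
sample_population <- function(cfg) {
  validate_config(cfg)
  n <- cfg$n_fishers
  reliability <- clip(stats::rnorm(n, cfg$reliability_mean, cfg$reliability_sd),
                      0, 1)
  skills <- pmax(stats::rnorm(n, cfg$skills_mean, cfg$skills_sd), 0)
  data.frame(id = seq_len(n),
             reliability = reliability,
             skills = skills,
             loyalty = 0,
             capital = cfg$initial_capital,
             affiliation = 0L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Reputation of a fisher
#'
#' The score buyers use when recruiting: the product of the fixed reliability
#' and fishing-skill traits.  Zero whenever either trait is zero.
#'
#' @param reliability Reliability in \[0, 1\].
#' @param skills Fishing skills (>= 0).
#' @return `reliability * skills` (vectorized).
#' @export
#' @examples
#' reputation(0.65, 0.5)   # 0.325
reputation <- function(reliability, skills) reliability * skills

#' Loyalty index
#'
#' Maps accumulated loyalty \eqn{l \ge 0} onto \[0, 1) with the saturating
#' form \eqn{l / (l + h)}, where the half-saturation \eqn{h} fixes the
#' loyalty at which the index reaches 0.5.  The index is the quantity the
#' cheating decision compares against a uniform draw, so \eqn{h} sets the
#' loyalty scale at which fishers become trustworthy.
#'
#' @param loyalty Non-negative loyalty (vectorized).
#' @param half_saturation Positive half-saturation constant \eqn{h}.
#' @return Values in \[0, 1); monotone nondecreasing in `loyalty`.
#' @export
#' @examples
#' loyalty_index(0, 40)     # 0
#' loyalty_index(40, 40)    # 0.5
loyalty_index <- function(loyalty, half_saturation = 40) {
  if (half_saturation <= 0) stop("half_saturation must be > 0", call. = FALSE)
  if (any(loyalty < 0)) stop("loyalty must be >= 0", call. = FALSE)
  loyalty / (loyalty + half_saturation)
}
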