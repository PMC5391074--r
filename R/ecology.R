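#' Daily catch-rate multiplier of the environmental regime
#'
#' In the deterministic and seasonal regimes the multiplier is 1 (seasonality
#' acts on the stock's carrying capacity, not on the daily catch draw).  In
#' the stochastic regime one unit-mean lognormal multiplier with coefficient
#' of variation `cv` is drawn per day and applied to every fisher's catch
#' rate, emulating shared weather-driven fluctuations.
#'
#' @param regime `"deterministic"`, `"stochastic"` or `"seasonal"`.
#' @param cv Coefficient of variation of the stochastic multiplier.
#' @param n Number of draws (days).
#' @return A numeric vector of positive multipliers with mean 1.
#' @export
#' @examples
#' catch_factor("deterministic")        # 1
#' set.seed(1); mean(catch_factor("stochastic", 0.3, 1e5))  # ~1
catch_factor <- function(regime, cv = 0.3, n = 1L) {
  if (regime != "stochastic") return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Seasonally forced carrying capacity
#'
#' \eqn{K_t = K (1 + a \sin(2\pi\,\mathrm{day}/365))}: the capacity equals
#' \eqn{K} in the non-seasonal regimes (\eqn{a = 0}) and at the
#' zero-crossings of the sine, peaks at \eqn{(1+a)K} a quarter year in, and
#' bottoms at \eqn{(1-a)K} three quarters in.  Amplitude \eqn{a < 1} keeps
#' the forcing positive.
#'
#' @param K Carrying capacity (biomass).
#' @param amplitude Relative amplitude \eqn{a} in \[0, 1).
#' @param day Day of year (0-based; vectorized).
#' @return Forced capacity \eqn{K_t}.
#' @export
#' @examples
#' seasonal_capacity(1000, 0.5, 0)        # 1000
#' seasonal_capacity(1000, 0.5, 365 / 4)  # 1500
seasonal_capacity <- function(K, amplitude, day) {
  K * (1 + amplitude * sin(2 * pi * day / 365))
}

#' Individual daily catch
#'
#' Linear (Gordon-Schaefer) harvest: a fisher of skill \eqn{s} removes
#' \eqn{q\,s\,N\,f} biomass, where \eqn{f} is the day's environmental catch
#' multiplier.  When the summed raw catches of all active fishers would
#' exceed the stock, all catches are scaled proportionally so the day's
#' harvest never exceeds \eqn{N} (preserving relative skill differences).
#'
#' @param skills Vector of fishing skills of the active fishers.
#' @param N Stock biomass.
#' @param q Catchability.
#' @param factor Environmental multiplier (>= 0).
#' @return Vector of catches, scaled so `sum(catch) <= N`.
#' @export
#' @examples
#' individual_catch(0.5, 1000, 0.001)   # 0.5
individual_catch <- function(skills, N, q, factor = 1) {
  raw <- q * skills * N * factor
  s <- sum(raw)
  if (s > N && s > 0) raw <- raw * (N / s)
  raw
}

#' One daily step of the fish stock
#'
#' Discrete-time (Euler, 365 steps/year) logistic update with harvest:
#' \deqn{N' = \max(0,\; N + r N (1 - N/K_t) - H),}
#' where \eqn{K_t} is the seasonally forced capacity of the current day and
#' \eqn{H} the day's total harvest.  The stock is floored at zero.
#'
#' @param N Current biomass.
#' @param day Day of year (0-based).
#' @param total_harvest Total biomass removed today (>= 0).
#' @param K,r Stock parameters.
#' @param amplitude Seasonal amplitude (0 outside the seasonal regime).
#' @return Biomass at the start of the next day.
#' @export
#' @examples
#' stock_step(500, 0, 0, K = 1000, r = 0.04)   # 505 = 500 + rK/4
stock_step <- function(N, day, total_harvest, K, r, amplitude = 0) {
  stopifnot(total_harvest >= 0)
  Kt <- seasonal_capacity(K, amplitude, day)
  max(0, N + r * N * (1 - N / Kt) - total_harvest)
}
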