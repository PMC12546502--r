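#' Discount a yearly series to present value
#'
#' With `timing = "immediate"` (the default) the value at year index `t` is
#' multiplied by `(1 + rate)^-t`, so Year 0 is unchanged. With
#' `timing = "end"` every year's flow — including Year 0's — is booked at the
#' end of its year and discounted one extra period, `(1 + rate)^-(t + 1)`.
#' The model's schedules use end-of-year timing, which is the convention
#' under which the published investment-table totals reproduce (see the
#' methods vignette).
#'
#' @param values Numeric vector of euro amounts, indexed from Year 0.
#' @param rate Annual discount rate, must exceed -1.
#' @param timing `"immediate"` or `"end"`.
#' @param years Optional integer year indices (default `0:(length(values)-1)`).
#' @return Numeric vector of discounted values, same length as `values`.
#' @examples
#' discount_series(c(0, rep(100, 7)), 0.05)
#' round(discount_series(c(rep(0, 7), 1.10e6), 0.05)[8])  # ~0.78m at Year 7
#' @export
discount_series <- function(values, rate, timing = c("immediate", "end"),
                            years = seq_along(values) - 1) {
  timing <- match.arg(timing)
  if (rate <= -1) {
    rlang::abort("discount rate must be greater than -1",
                 class = "dpnpv_validation_error")
  }
  shift <- if (timing == "end") 1 else 0
  values * (1 + rate)^(-(years + shift))
}

#' Discount factors for a forecast grid
#'
#' @param horizon Number of forecast years beyond Year 0.
#' @param rate Annual discount rate.
#' @param timing See [discount_series()].
#' @return Numeric vector of length `horizon + 1` of factors for Years
#'   `0..horizon`.
#' @export
discount_factors <- function(horizon, rate, timing = c("immediate", "end")) {
  discount_series(rep(1, horizon + 1), rate, timing)
}

## Capture-ramp family: phase-in of DP-enabled capture.
## ramp(0) = 0; ramp(t) = start + (1 - start) * ((t-1)/(h-1))^shape for t >= 1,
## so ramp(1) = start and ramp(h) = 1. Monotone in t for shape > 0.
capture_ramp <- function(horizon, start, shape) {
  t <- 0:horizon
  if (horizon == 1) return(c(0, 1))
  w <- start + (1 - start) * (pmax(t - 1, 0) / (horizon - 1))^shape
  w[1] <- 0
  w
}

## Phase profile for per-year staffing / savings levels:
## Year 0 = start, Years 1..(h-2) = base, linear from base to end over the
## last two years (so Year h-1 is the midpoint and Year h = end).
phase_profile <- function(horizon, start, base, end) {
  if (horizon == 1) return(c(start, end))
  t <- 1:horizon
  knee <- horizon - 2
  mid <- ifelse(t <= knee, base, base + (end - base) * (t - knee) / 2)
  c(start, mid)
}
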