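#' Natural-history parameters for the screening model
#'
#' Bundles the four parameters of the two-state (asymptomatic preclinical ->
#' symptomatic clinical) progression-and-detection model: the sojourn
#' transition rate, screening test sensitivity, and the advanced-stage
#' (node-positive) fractions among screen-detected and interval cancers.
#'
#' Defaults correspond to mammography screening of women aged 50-70:
#' a transition rate of 0.25/year from randomized-trial evidence, test
#' sensitivity 0.92, and node-positive fractions of 22% among screen-detected
#' and 53% among interval cancers.
#'
#' @param lambda_rate Transition rate (per year) from asymptomatic to
#'   symptomatic disease; must be positive.
#' @param sensitivity Probability a screen detects preclinical disease,
#'   in \[0, 1\]. Zero is accepted and handled by continuity (nothing is
#'   screen-detected) so sensitivity sweeps can touch the boundary.
#' @param adv_frac_screen Probability a screen-detected cancer is advanced
#'   (node-positive), in \[0, 1\].
#' @param adv_frac_interval Probability an interval cancer is advanced, in
#'   \[0, 1\].
#' @return An object of class `nh_params`.
#' @examples
#' nh_params()
#' nh_params(lambda_rate = 0.2, sensitivity = 0.85)
#' @export
nh_params <- function(lambda_rate = 0.25, sensitivity = 0.92,
                      adv_frac_screen = 0.22, adv_frac_interval = 0.53) {
  stopifnot(is.numeric(lambda_rate), length(lambda_rate) == 1L,
            is.finite(lambda_rate),
            is.numeric(sensitivity), length(sensitivity) == 1L,
            is.numeric(adv_frac_screen), length(adv_frac_screen) == 1L,
            is.numeric(adv_frac_interval), length(adv_frac_interval) == 1L)
  if (lambda_rate <= 0)
    stop("`lambda_rate` must be > 0", call. = FALSE)
  if (sensitivity < 0 || sensitivity > 1)
    stop("`sensitivity` must lie in [0, 1]", call. = FALSE)
  if (adv_frac_screen < 0 || adv_frac_screen > 1)
    stop("`adv_frac_screen` must lie in [0, 1]", call. = FALSE)
  if (adv_frac_interval < 0 || adv_frac_interval > 1)
    stop("`adv_frac_interval` must lie in [0, 1]", call. = FALSE)
  structure(
    list(lambda_rate = lambda_rate, sensitivity = sensitivity,
         adv_frac_screen = adv_frac_screen,
         adv_frac_interval = adv_frac_interval),
    class = "nh_params")
}

#' @export
print.nh_params <- function(x, ...) {
  cat("Natural-history parameters\n")
  cat(sprintf("  transition rate (lambda): %.4g /year\n", x$lambda_rate))
  cat(sprintf("  test sensitivity (D):     %.4g\n", x$sensitivity))
  cat(sprintf("  P(advanced | screen):     %.4g\n", x$adv_frac_screen))
  cat(sprintf("  P(advanced | interval):   %.4g\n", x$adv_frac_interval))
  invisible(x)
}

#' Define a screening regimen
#'
#' A regimen is an inter-screen interval together with its per-person cost,
#' counted as the number of screens over the planning horizon. Under the
#' default costing rule `cost = horizon_years / interval_years`; e.g. over a
#' 6-year horizon a biennial regimen costs 3 screens and a triennial regimen
#' costs 2.
#'
#' @param interval_years Inter-screen interval in years (> 0).
#' @param label Regimen label; defaults to e.g. `"3y"`.
#' @param cost Screens per person over the horizon; may be non-integer
#'   (a 4-year interval over 6 years costs 1.5). Defaults to
#'   `horizon_years / interval_years`.
#' @param horizon_years Planning horizon used by the default costing rule.
#' @return An object of class `regimen`.
#' @examples
#' regimen(3)                  # triennial: cost 2 over 6 years
#' regimen(4)$cost             # 1.5
#' @export
regimen <- function(interval_years, label = paste0(format(interval_years), "y"),
                    cost = NULL, horizon_years = 6) {
  stopifnot(is.numeric(interval_years), length(interval_years) == 1L,
            is.numeric(horizon_years), length(horizon_years) == 1L)
  if (!is.finite(interval_years) || interval_years <= 0)
    stop("`interval_years` must be > 0", call. = FALSE)
  if (!is.finite(horizon_years) || horizon_years <= 0)
    stop("`horizon_years` must be > 0", call. = FALSE)
  if (is.null(cost)) cost <- horizon_years / interval_years
  if (!is.finite(cost) || cost <= 0)
    stop("`cost` must be > 0", call. = FALSE)
  structure(list(label = as.character(label),
                 interval_years = interval_years,
                 cost = cost),
            class = "regimen")
}

#' Build a list of regimens from their intervals
#'
#' @param intervals Numeric vector of inter-screen intervals (years).
#' @param horizon_years Planning horizon for the default costing rule.
#' @return A list of [regimen()] objects.
#' @examples
#' regimen_set(c(1, 3, 4))
#' @export
regimen_set <- function(intervals, horizon_years = 6) {
  stopifnot(length(intervals) >= 1L)
  lapply(intervals, regimen, horizon_years = horizon_years)
}

#' Proportion of cancers that are screen-detected
#'
#' Closed-form probability that a cancer arising under periodic screening is
#' detected at a screen rather than diagnosed symptomatically in the interval
#' between screens. The model assumes an exponential sojourn time in the
#' asymptomatic screen-detectable phase (rate `lambda_rate`), screens every
#' `interval_years` with per-screen sensitivity `D`, and preclinical onset
#' uniform within a screening round:
#'
#' \deqn{s = \frac{D\,(1 - e^{-\lambda u})}
#'               {\lambda u \,\{1 - (1 - D)\,e^{-\lambda u}\}}}
#'
#' `D = 0` returns 0 by continuity (documented special case). The function is
#' vectorized over `interval_years`.
#'
#' @param params An [nh_params()] object.
#' @param interval_years Inter-screen interval(s) in years, all > 0.
#' @return Probability (or vector of probabilities) in \[0, 1\].
#' @examples
#' p <- nh_params()
#' screen_detected_fraction(p, 1)  # ~0.87
#' screen_detected_fraction(p, 3)  # ~0.67
#' @export
screen_detected_fraction <- function(params, interval_years) {
  stopifnot(inherits(params, "nh_params"), is.numeric(interval_years))
  if (length(interval_years) == 0L)
    stop("`interval_years` must be non-empty", call. = FALSE)
  if (any(!is.finite(interval_years)) || any(interval_years <= 0))
    stop("`interval_years` must be > 0", call. = FALSE)
  D <- params$sensitivity
  if (D == 0) return(rep(0, length(interval_years)))
  lu <- params$lambda_rate * interval_years
  e <- exp(-lu)
  D * (1 - e) / (lu * (1 - (1 - D) * e))
}

#' Advanced-stage fraction given the screen-detected fraction
#'
#' Mixes the stage distribution over detection mode: a cancer detected at a
#' screen is advanced with probability `a`, an interval cancer with
#' probability `b`, so the overall advanced fraction is `a*s + b*(1 - s)`.
#' The result always lies between `min(a, b)` and `max(a, b)`; with `b > a`
#' (the usual case) it decreases as screening detects a larger share.
#'
#' @param params An [nh_params()] object supplying `a` and `b`.
#' @param s Screen-detected fraction(s) in \[0, 1\].
#' @return Probability (vectorized over `s`).
#' @examples
#' p <- nh_params()
#' advanced_fraction(p, screen_detected_fraction(p, 3))  # ~0.32
#' @export
advanced_fraction <- function(params, s) {
  stopifnot(inherits(params, "nh_params"), is.numeric(s))
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("`s` must lie in [0, 1]", call. = FALSE)
  params$adv_frac_screen * s + params$adv_frac_interval * (1 - s)
}

#' Advanced-cancer risk for a risk stratum under a regimen
#'
#' Extends an invasive-cancer risk `r` to advanced-cancer risk by the
#' detection-mode adjustment factor:
#' `p = r * (a*s + b*(1 - s))` with `s` the screen-detected fraction for the
#' regimen's interval. Always `p <= r`, with equality only when `a = b = 1`.
#'
#' @param invasive_risk Invasive-cancer risk(s) over the projection horizon,
#'   in \[0, 1\].
#' @param params An [nh_params()] object.
#' @param regimen A [regimen()] object.
#' @return Advanced-cancer probability (vectorized over `invasive_risk`).
#' @examples
#' advanced_risk(0.01, nh_params(), regimen(3))  # ~0.0032
#' @export
advanced_risk <- function(invasive_risk, params, regimen) {
  stopifnot(is.numeric(invasive_risk), inherits(regimen, "regimen"))
  if (any(!is.finite(invasive_risk)) ||
      any(invasive_risk < 0) || any(invasive_risk > 1))
    stop("`invasive_risk` must lie in [0, 1]", call. = FALSE)
  s <- screen_detected_fraction(params, regimen$interval_years)
  invasive_risk * advanced_fraction(params, s)
}

#' Expected detection-mode and stage mix by screening interval
#'
#' Tabulates, for each candidate interval, the percentage of cancers expected
#' to be screen-detected and the percentage expected to be advanced
#' (node-positive), rounded to the nearest integer percent (half away from
#' zero). Underlying values are kept at full precision everywhere else in the
#' package; rounding here is presentation only.
#'
#' @param params An [nh_params()] object.
#' @param intervals Screening intervals in years; default `1:5` matches the
#'   default regimen grid.
#' @return A data.frame with columns `interval_years`, `screen_detected_pct`,
#'   `advanced_pct`.
#' @examples
#' node_positive_table(nh_params(), 1:4)
#' @export
node_positive_table <- function(params, intervals = 1:5) {
  stopifnot(inherits(params, "nh_params"))
  if (length(intervals) == 0L)
    stop("`intervals` must be non-empty", call. = FALSE)
  s <- screen_detected_fraction(params, intervals)
  adv <- advanced_fraction(params, s)
  data.frame(interval_years = intervals,
             screen_detected_pct = round_half_away(100 * s),
             advanced_pct = round_half_away(100 * adv))
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
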