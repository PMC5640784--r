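# Physiology mapping: 4-parameter logistic (Hill) dose-response fitting,
# inversion of phospho-STAT3 signals to equivalent IL-6 concentrations, and
# mouse/human IL-6 potency conversion.

#' Evaluate a 4-parameter logistic (Hill) curve
#'
#' y = y_min + (y_max - y_min) / (1 + (ec50 / d)^h), increasing in dose.
#'
#' @param dose dose(s), same unit as `ec50` (ng/mL here); dose 0 maps to
#'   y_min.
#' @param y_min,y_max lower/upper asymptotes (signal a.u.).
#' @param ec50 half-maximum dose.
#' @param hill Hill coefficient (> 0).
#' @return signal value(s).
#' @export
hill4 <- function(dose, y_min, y_max, ec50, hill) {
  out <- ifelse(dose <= 0, y_min,
                y_min + (y_max - y_min) / (1 + (ec50 / dose)^hill))
  as.numeric(out)
}

#' Fit a 4-parameter logistic curve by least squares
#'
#' Levenberg-Marquardt least squares with deterministic multi-start over
#' ec50 and Hill coefficient. Requires dose levels bracketing the
#' half-maximum; a fit whose data do not bracket it is flagged unreliable.
#'
#' @param doses dose vector (>= 5 distinct positive levels recommended).
#' @param signals matched signal vector.
#' @return object of class `hep_hill_fit` with elements `y_min`, `y_max`,
#'   `ec50`, `hill`, `rss`, `reliable`, `fit` (the nls object).
#' @export
fit_hill4 <- function(doses, signals) {
  stopifnot(length(doses) == length(signals))
  keep <- is.finite(doses) & is.finite(signals)
  d <- doses[keep]; y <- signals[keep]
  if (length(unique(d[d > 0])) < 4) {
    stop("need at least 4 distinct positive dose levels", call. = FALSE)
  }
  rng <- range(y)
  starts <- expand.grid(
    ec50 = stats::quantile(d[d > 0], c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ hill4(d, y_min, y_max, ec50, hill),
        start = list(y_min = rng[1], y_max = rng[2],
                     ec50 = starts$ec50[i], hill = starts$hill[i]),
        lower = c(-Inf, -Inf, 1e-8, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("4PL fit failed from all starts", call. = FALSE)
  cf <- stats::coef(best$fit)
  # reliability is judged against the *fitted* curve: the data must straddle
  # the fitted half-maximum and the fitted EC50 must lie inside the tested
  # dose range, otherwise the transition is extrapolated
  half_fit <- (cf[["y_min"]] + cf[["y_max"]]) / 2
  dpos <- d[d > 0]
  reliable <- cf[["y_max"]] > cf[["y_min"]] &&
    any(y < half_fit) && any(y > half_fit) &&
    cf[["ec50"]] >= min(dpos) && cf[["ec50"]] <= max(dpos) &&
    length(unique(dpos)) >= 5
  structure(
    list(y_min = cf[["y_min"]], y_max = cf[["y_max"]],
         ec50 = cf[["ec50"]], hill = cf[["hill"]],
         rss = best$rss, reliable = reliable, fit = best$fit),
    class = "hep_hill_fit"
  )
}

#' @export
print.hep_hill_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: y_min %.4g, y_max %.4g, EC50 %.4g ng/mL, Hill %.3g (RSS %.4g)%s\n",
    x$y_min, x$y_max, x$ec50, x$hill, x$rss,
    if (x$reliable) "" else " [unreliable: half-maximum not bracketed]"))
  invisible(x)
}

# exact inverse of the 4PL on its open range (y_min, y_max)
.invert_hill4 <- function(fit, y) {
  span <- fit$y_max - fit$y_min
  frac <- (y - fit$y_min) / span
  fit$ec50 / (1 / frac - 1)^(1 / fit$hill)
}

#' Invert a phospho-STAT3 signal to an equivalent IL-6 interval
#'
#' Inverts the fitted 4PL at mean - sem, mean and mean + sem. Signals above
#' the curve range are censored at the top calibration dose; signals below
#' the range are censored at "< lowest dose".
#'
#' @param fit a `hep_hill_fit`.
#' @param signal_mean,signal_sem signal mean and its standard error.
#' @param top_dose top calibration dose (default 500 ng/mL).
#' @param bottom_dose lowest calibration dose (default 0.1 ng/mL).
#' @return list with `lower`, `upper`, `midpoint` (ng/mL; midpoint rounded
#'   half-up to one decimal), `censored_low`, `censored_high`.
#' @export
invert_signal <- function(fit, signal_mean, signal_sem = 0,
                          top_dose = 500, bottom_dose = 0.1) {
  inv_one <- function(y) {
    if (y >= fit$y_max) return(list(d = top_dose, lo = FALSE, hi = TRUE))
    if (y <= fit$y_min) return(list(d = bottom_dose, lo = TRUE, hi = FALSE))
    d <- .invert_hill4(fit, y)
    if (d > top_dose) return(list(d = top_dose, lo = FALSE, hi = TRUE))
    if (d < bottom_dose) return(list(d = bottom_dose, lo = TRUE, hi = FALSE))
    list(d = d, lo = FALSE, hi = FALSE)
  }
  lo <- inv_one(signal_mean - signal_sem)
  hi <- inv_one(signal_mean + signal_sem)
  mid <- round_half_up((lo$d + hi$d) / 2, 1)
  list(lower = lo$d, upper = hi$d, midpoint = mid,
       censored_low = lo$lo, censored_high = hi$hi)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 7.35
#' rounds to 7.4), the convention used for reported interval midpoints.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Convert IL-6 doses between human and mouse potency scales
#'
#' On mouse hepatocytes, 1.8 ng of mouse IL-6 is as potent as 7.5 ng of
#' human IL-6: human -> mouse divides by 7.5/1.8, mouse -> human multiplies.
#'
#' @param dose dose (ng/mL), >= 0.
#' @param direction "human_to_mouse" or "mouse_to_human".
#' @param factor potency ratio (default 7.5/1.8).
#' @return converted dose.
#' @export
potency_convert <- function(dose, direction = c("human_to_mouse",
                                                "mouse_to_human"),
                            factor = 7.5 / 1.8) {
  direction <- match.arg(direction)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (direction == "human_to_mouse") dose / factor else dose * factor
}
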