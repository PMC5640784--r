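# Local parameter sensitivity analysis of the integrated acute-phase
# response: relative change of the integrated mRNA output per relative
# parameter change, per gene and averaged over genes, with min/max envelopes
# over profile-likelihood-consistent parameter sets.

#' Integrated mRNA response of one gene
#'
#' Integral of the cytoplasmic mRNA concentration over \[0, horizon\] under
#' continuous IL-6 from t = 0. The default method reads the appended
#' cumulative-integral state from the solver; `method = "trapezoid"`
#' integrates a dense trajectory by the trapezoidal rule as an independent
#' cross-check.
#'
#' @param network reference network containing the gene.
#' @param params full parameter vector.
#' @param gene gene name.
#' @param il6 IL-6 concentration (ng/mL).
#' @param horizon upper limit of the integral (hours).
#' @param method "ode" (integral state) or "trapezoid".
#' @param dt trapezoid step (hours) when `method = "trapezoid"`.
#' @param schedule optional [rux_schedule()] applied during the simulation.
#' @return integral in nM * h.
#' @export
integrated_response <- function(network, params, gene, il6 = 100,
                                horizon = 24, method = c("ode", "trapezoid"),
                                dt = 0.01, schedule = NULL) {
  method <- match.arg(method)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  ev <- dose_event(0, "IL6", il6, "set")
  if (!is.null(schedule)) {
    se <- .schedule_events(schedule)
    if (!is.null(se)) ev <- rbind(ev, se)
  }
  if (method == "ode") {
    pr <- protocol(ev, c(0, horizon))
    tr <- simulate_protocol(network, params, pr)
    return(as.numeric(trajectory_states(tr, horizon)[, paste0("IntRNA_", gene)]))
  }
  grid <- seq(0, horizon, by = dt)
  pr <- protocol(ev, grid)
  tr <- simulate_protocol(network, params, pr)
  y <- trajectory_states(tr, grid)[, paste0("AppRNA_", gene)]
  sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
}

# integrals for all genes from one simulation
.integrated_all <- function(network, params, il6, horizon) {
  pr <- stimulation_protocol(il6, c(0, horizon))
  tr <- simulate_protocol(network, params, pr)
  genes <- names(network$genes)
  stats::setNames(
    as.numeric(trajectory_states(tr, horizon)[, paste0("IntRNA_", genes)]),
    genes)
}

#' Local parameter sensitivity analysis of the integrated APP response
#'
#' For each parameter p, perturbs it by `perturbation` (default +50%),
#' recomputes the integrated mRNA response y of every acute-phase gene, and
#' reports the relative sensitivity
#' S = ((y - y_ref)/y_ref) / ((p - p_ref)/p_ref) per gene and its arithmetic
#' mean over genes. The reference output is computed once and reused.
#'
#' @param network reference network (core + genes).
#' @param params full parameter vector.
#' @param parameters parameter names to perturb (default: all dynamic
#'   parameters of the network).
#' @param perturbation relative perturbation (0.5 = +50%; negative values
#'   perturb downward).
#' @param il6 IL-6 level (ng/mL).
#' @param horizon integration horizon (hours).
#' @return data.frame of class `hep_lpsa`: parameter, per-gene sensitivities
#'   (columns S_<gene>), mean sensitivity S_mean.
#' @export
lpsa <- function(network, params, parameters = network$parameters,
                 perturbation = 0.5, il6 = 100, horizon = 24) {
  y_ref <- .integrated_all(network, params, il6, horizon)
  if (any(y_ref <= 0)) {
    stop("reference integrated response must be positive for all genes",
         call. = FALSE)
  }
  genes <- names(y_ref)
  rows <- lapply(parameters, function(pn) {
    p2 <- params
    p2[pn] <- params[[pn]] * (1 + perturbation)
    y <- tryCatch(.integrated_all(network, p2, il6, horizon),
                  error = function(e) rep(NA_real_, length(genes)))
    s <- ((y - y_ref) / y_ref) / perturbation
    data.frame(parameter = pn,
               t(stats::setNames(s, paste0("S_", genes))),
               S_mean = mean(s), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hep_lpsa", "data.frame")
  attr(out, "perturbation") <- perturbation
  attr(out, "il6") <- il6
  attr(out, "horizon") <- horizon
  out
}

#' Sensitivity envelopes over profile-consistent parameter sets
#'
#' Re-evaluates the mean sensitivity of each perturbed parameter at every
#' parameter vector stored in the supplied profiles whose objective lies
#' within the confidence threshold of the best objective, and reports the
#' min/max envelope around the point estimate.
#'
#' @param network,params as in [lpsa()].
#' @param profiles list of `hep_profile` objects (each profiled parameter
#'   grid supplies alternative parameter vectors: the profiled parameter is
#'   set to each in-interval grid value).
#' @param parameters parameters whose sensitivity is enveloped.
#' @param threshold objective increase defining inclusion (default: each
#'   profile's own threshold).
#' @param ... passed to [lpsa()] (perturbation, il6, horizon).
#' @return data.frame: parameter, S_mean (point estimate), S_min, S_max.
#' @export
lpsa_uncertainty <- function(network, params, profiles,
                             parameters = network$parameters,
                             threshold = NULL, ...) {
  if (!length(profiles)) stop("empty profile set", call. = FALSE)
  point <- lpsa(network, params, parameters, ...)
  s_min <- s_max <- stats::setNames(point$S_mean, point$parameter)
  for (pr in profiles) {
    thr <- if (is.null(threshold)) pr$threshold else threshold
    keep <- pr$profile$objective <= pr$best_objective + thr
    for (v in pr$profile$value[keep]) {
      p2 <- params
      p2[pr$param] <- v
      s <- lpsa(network, p2, parameters, ...)
      s_min <- pmin(s_min, stats::setNames(s$S_mean, s$parameter))
      s_max <- pmax(s_max, stats::setNames(s$S_mean, s$parameter))
    }
  }
  data.frame(parameter = point$parameter, S_mean = point$S_mean,
             S_min = as.numeric(s_min[point$parameter]),
             S_max = as.numeric(s_max[point$parameter]),
             row.names = NULL)
}
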