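# Ruxolitinib dosing-schedule design: bolus plus equal-interval top-ups
# under a concentration cap, evaluated by the integrated acute-phase mRNA
# response to inflammatory IL-6 up to 24 h.

#' Construct a Ruxolitinib dosing schedule
#'
#' @param times dose times (hours), at most 3 doses.
#' @param doses dose amounts (nM), matched to `times`.
#' @param cap concentration cap (nM); the predicted concentration must never
#'   exceed it.
#' @param label schedule label (e.g. "Single", "Triple").
#' @return object of class `hep_schedule`.
#' @export
rux_schedule <- function(times, doses, cap = 500, label = "schedule") {
  stopifnot(length(times) == length(doses))
  if (length(times) > 3) {
    stop("at most 3 doses per schedule", call. = FALSE)
  }
  if (any(doses < 0)) stop("negative dose", call. = FALSE)
  o <- order(times)
  structure(list(times = times[o], doses = doses[o], cap = cap,
                 label = label),
            class = "hep_schedule")
}

#' The Single and Triple reference dosing schedules
#' @param cap concentration cap in nM.
#' @return named list of two schedules.
#' @export
reference_schedules <- function(cap = 500) {
  list(
    Single = rux_schedule(-1, 500, cap, "Single"),
    Triple = rux_schedule(c(0, 8, 16), c(500, 191, 191), cap, "Triple")
  )
}

#' Top-up dose restoring a decayed bolus
#'
#' dose = D0 * (1 - exp(-k * interval)): adding it every `interval` hours
#' restores the concentration exactly to the bolus level D0.
#'
#' @param D0 bolus concentration (nM), > 0.
#' @param k_rux_deg first-order decay rate (1/h), >= 0.
#' @param interval dosing interval (hours), > 0.
#' @return top-up dose (nM).
#' @export
compute_topup <- function(D0, k_rux_deg, interval) {
  if (D0 <= 0 || k_rux_deg < 0 || interval <= 0) {
    stop("D0 and interval must be positive, k_rux_deg >= 0", call. = FALSE)
  }
  D0 * (1 - exp(-k_rux_deg * interval))
}

# schedule -> dose events for simulate_protocol
.schedule_events <- function(schedule) {
  if (!length(schedule$times)) return(NULL)
  do.call(rbind, lapply(seq_along(schedule$times), function(i) {
    dose_event(schedule$times[i], "Ruxolitinib", schedule$doses[i], "add")
  }))
}

#' Evaluate a dosing schedule by integrated gene responses
#'
#' Simulates the full model under the schedule plus continuous IL-6 from
#' t = 0 and returns, per gene, the integrated cytoplasmic mRNA over
#' \[0, horizon\] (absolute and normalized to the no-inhibitor response) and
#' the mRNA level at the horizon. The closed-form inhibitor concentration is
#' checked against the cap before simulating.
#'
#' @param network reference network (core + genes).
#' @param params full parameter vector.
#' @param schedule a [rux_schedule()] (empty times = no inhibitor).
#' @param il6 IL-6 concentration (ng/mL), default 100 (inflammatory).
#' @param horizon integration horizon (hours).
#' @return object of class `hep_schedule_eval`: data.frame with gene,
#'   integral, integral_normalized, expr_at_horizon, plus attributes.
#' @export
evaluate_schedule <- function(network, params, schedule, il6 = 100,
                              horizon = 24) {
  conc <- inhibitor_profile(schedule, params[["k_rux_deg"]])
  tchk <- sort(unique(c(schedule$times, seq(min(c(schedule$times, 0)),
                                            horizon, length.out = 481))))
  cc <- conc(tchk)
  if (any(cc > schedule$cap * (1 + 1e-9))) {
    stop(sprintf("schedule exceeds cap %g nM at t = %g h",
                 schedule$cap, tchk[which.max(cc)]), call. = FALSE)
  }
  genes <- names(network$genes)
  run <- function(sched) {
    ev <- dose_event(0, "IL6", il6, "set")
    se <- .schedule_events(sched)
    if (!is.null(se)) ev <- rbind(ev, se)
    tr <- simulate_protocol(network, params, protocol(ev, c(0, horizon)))
    s <- trajectory_states(tr, horizon)
    list(integ = s[, paste0("IntRNA_", genes), drop = TRUE],
         expr = s[, paste0("AppRNA_", genes), drop = TRUE])
  }
  with_inh <- run(schedule)
  no_inh <- run(rux_schedule(numeric(0), numeric(0), schedule$cap, "none"))
  out <- data.frame(
    gene = genes,
    integral = as.numeric(with_inh$integ),
    integral_noinhibitor = as.numeric(no_inh$integ),
    integral_normalized = as.numeric(with_inh$integ / no_inh$integ),
    expr_at_horizon = as.numeric(with_inh$expr),
    row.names = NULL
  )
  structure(out, class = c("hep_schedule_eval", "data.frame"),
            schedule = schedule, il6 = il6, horizon = horizon)
}

#' Design a capped Ruxolitinib schedule
#'
#' Enumerates candidate schedules (bolus at t in `bolus_times`, bolus size
#' over a grid up to the cap, 1-3 doses with top-ups from [compute_topup()]
#' at even intervals over the horizon), evaluates each by
#' [evaluate_schedule()], and returns the schedule minimizing the mean
#' normalized integrated response over all genes. Ties (within 1e-9) are
#' broken toward fewer doses. The full per-candidate response-curve table is
#' returned for inspection.
#'
#' @param network,params reference network and parameter vector.
#' @param cap concentration cap (nM).
#' @param max_doses maximum number of doses (<= 3).
#' @param horizon horizon (hours).
#' @param il6 IL-6 level (ng/mL).
#' @param bolus_times candidate first-dose times (hours).
#' @param bolus_grid candidate bolus sizes as fractions of the cap.
#' @return list with `best` (a `hep_schedule`), `curves` (data.frame of all
#'   candidates with per-gene normalized integrals and the mean objective).
#' @export
design_schedule <- function(network, params, cap = 500, max_doses = 3,
                            horizon = 24, il6 = 100,
                            bolus_times = c(-1, 0),
                            bolus_grid = c(0.25, 0.5, 0.75, 1)) {
  k <- params[["k_rux_deg"]]
  cands <- list()
  for (t0 in bolus_times) {
    for (f in bolus_grid) {
      D0 <- f * cap
      for (n in seq_len(max_doses)) {
        if (n == 1) {
          sched <- rux_schedule(t0, D0, cap,
                                sprintf("n1_t%g_D%g", t0, D0))
        } else {
          interval <- horizon / n
          topup <- compute_topup(D0, k, interval)
          times <- t0 + interval * (seq_len(n) - 1)
          sched <- rux_schedule(times, c(D0, rep(topup, n - 1)), cap,
                                sprintf("n%d_t%g_D%g", n, t0, D0))
        }
        cands[[length(cands) + 1]] <- sched
      }
    }
  }
  if (!length(cands)) stop("empty candidate set", call. = FALSE)
  rows <- lapply(cands, function(s) {
    ev <- evaluate_schedule(network, params, s, il6, horizon)
    data.frame(label = s$label, n_doses = length(s$times),
               bolus_time = s$times[1], bolus = s$doses[1],
               objective = mean(ev$integral_normalized),
               t(stats::setNames(ev$integral_normalized,
                                 paste0("norm_", ev$gene))),
               row.names = NULL)
  })
  curves <- do.call(rbind, rows)
  best_obj <- min(curves$objective)
  tied <- which(curves$objective <= best_obj + 1e-9)
  best_i <- tied[which.min(curves$n_doses[tied])]
  list(best = cands[[best_i]], curves = curves)
}

#' Scale a schedule for a more inhibitor-sensitive species
#'
#' Divides all doses by `factor` and rounds to the nearest integer nM
#' (mouse -> human uses factor 10: 500/191/191 -> 50/19/19); times and cap
#' semantics are unchanged.
#'
#' @param schedule a `hep_schedule`.
#' @param factor sensitivity factor (> 0).
#' @return scaled `hep_schedule`.
#' @export
scale_for_species <- function(schedule, factor) {
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  rux_schedule(schedule$times, round(schedule$doses / factor),
               cap = schedule$cap / factor,
               label = paste0(schedule$label, sprintf("_scaled%g", factor)))
}

#' Inhibitor concentration halving the peak pSTAT3 response
#'
#' Simulates IL-6/Ruxolitinib co-treatment (both added at t = 0) over a
#' log-spaced dose grid, computes the peak pSTAT3 rise above the
#' pre-stimulation level for each dose, and log-interpolates the 50%
#' crossing relative to the uninhibited response.
#'
#' @param network a network containing the core model.
#' @param params parameter vector.
#' @param il6 IL-6 concentration (ng/mL).
#' @param doses inhibitor dose grid (nM), log-spaced, must bracket the 50%
#'   crossing.
#' @param horizon simulation horizon for the peak search (hours).
#' @return IC50 in nM.
#' @export
ic50 <- function(network, params, il6 = 40,
                 doses = 10^seq(1, 4, length.out = 13), horizon = 2) {
  grid <- seq(0, horizon, by = 1 / 60)
  peak_rise <- function(rux) {
    ev <- dose_event(0, "IL6", il6, "set")
    if (rux > 0) ev <- rbind(ev, dose_event(0, "Ruxolitinib", rux, "add"))
    tr <- simulate_protocol(network, params, protocol(ev, grid))
    ps <- tr$states[, "pSTAT3"]
    max(ps) - ps[1]
  }
  r0 <- peak_rise(0)
  rel <- vapply(doses, peak_rise, numeric(1)) / r0
  if (any(diff(rel) > 1e-6)) {
    stop("response not monotone over the dose grid", call. = FALSE)
  }
  if (!(any(rel >= 0.5) && any(rel <= 0.5))) {
    stop("response does not bracket 50% over the dose grid", call. = FALSE)
  }
  i <- max(which(rel >= 0.5))
  ld <- log10(doses)
  10^(ld[i] + (0.5 - rel[i]) * (ld[i + 1] - ld[i]) / (rel[i + 1] - rel[i]))
}
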