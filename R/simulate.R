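# Simulation engine: steady-state pre-equilibration, event-driven piecewise
# integration (IL-6 set/wash, Ruxolitinib bolus with first-order decay,
# Stattic and ActD held constant), dense trajectories.

#' Construct a dose event
#'
#' @param time event time in hours (negative = pre-treatment; t = 0 is IL-6
#'   addition by convention).
#' @param channel one of "IL6", "Ruxolitinib", "Stattic", "ActD".
#' @param amount dose in channel units (IL-6 ng/mL, inhibitors nM, ActD
#'   treated as an on/off flag: any positive amount blocks transcription).
#' @param mode "set" (IL6, Stattic, ActD), "add" (Ruxolitinib bolus onto the
#'   decaying state) or "wash" (IL6 to zero).
#' @return one-row data.frame.
#' @export
dose_event <- function(time, channel, amount, mode = "set") {
  channel <- match.arg(channel, c("IL6", "Ruxolitinib", "Stattic", "ActD"))
  mode <- match.arg(mode, c("set", "add", "wash"))
  if (amount < 0) stop("dose amount must be >= 0", call. = FALSE)
  if (channel == "Ruxolitinib" && mode != "add") {
    stop("Ruxolitinib doses use mode = 'add'", call. = FALSE)
  }
  if (channel %in% c("Stattic", "ActD") && mode != "set") {
    stop(channel, " uses mode = 'set'", call. = FALSE)
  }
  if (mode == "wash" && channel != "IL6") {
    stop("wash applies to IL6 only", call. = FALSE)
  }
  data.frame(time = time, channel = channel,
             amount = if (mode == "wash") 0 else amount,
             mode = mode, stringsAsFactors = FALSE)
}

#' Construct an experimental protocol
#'
#' @param events data.frame of [dose_event()] rows (rbind them), or NULL for
#'   an unstimulated protocol.
#' @param observation_times times (hours) at which observables are read out.
#' @param pre_equilibrate equilibrate to the unstimulated steady state before
#'   the earliest event (default TRUE).
#' @param label protocol label.
#' @return object of class `hep_protocol`.
#' @export
protocol <- function(events = NULL, observation_times,
                     pre_equilibrate = TRUE, label = "protocol") {
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), channel = character(0),
                         amount = numeric(0), mode = character(0),
                         stringsAsFactors = FALSE)
  }
  events <- events[order(events$time), , drop = FALSE]
  structure(
    list(events = events,
         observation_times = sort(unique(observation_times)),
         pre_equilibrate = pre_equilibrate,
         label = label),
    class = "hep_protocol"
  )
}

#' Single-stimulus convenience protocol
#'
#' Continuous IL-6 from t = 0, optional inhibitor events.
#'
#' @param il6 IL-6 concentration in ng/mL.
#' @param times observation times (hours).
#' @param extra_events optional additional dose events.
#' @param label protocol label.
#' @return `hep_protocol`.
#' @export
stimulation_protocol <- function(il6, times, extra_events = NULL,
                                 label = sprintf("IL6_%g", il6)) {
  ev <- dose_event(0, "IL6", il6, "set")
  if (!is.null(extra_events)) ev <- rbind(ev, extra_events)
  protocol(ev, times, label = label)
}

.default_inputs <- function() c(IL6 = 0, Stattic = 0, ActD = 0)

.ode_parms <- function(params, inputs) {
  c(as.list(params), as.list(inputs))
}

#' Equilibrate the network to its unstimulated steady state
#'
#' All inputs are held at zero. The primary method integrates until the
#' largest time derivative falls below `tol`; `method = "root"` refines a
#' shorter integration by Newton iterations using the analytic Jacobian,
#' with a pseudoinverse step that respects the conserved STAT3 total.
#'
#' @param network a `hep_network`.
#' @param params named parameter values covering `network$parameters`.
#' @param tol steady-state tolerance on max |dy/dt| (nM/h).
#' @param method "integrate" or "root".
#' @param t_max integration horizon (hours) for the integrate method.
#' @param time experiment time at which slow basal drifts are frozen
#'   (default 0, the stimulation start); the equilibration ODE must be
#'   autonomous for a steady state to exist.
#' @return named steady-state vector.
#' @export
equilibrate <- function(network, params, tol = 1e-10,
                        method = c("integrate", "root"), t_max = 1e5,
                        time = 0) {
  method <- match.arg(method)
  network <- compile_network(network)
  parms <- .ode_parms(params, .default_inputs())
  rhs0 <- network$compiled$rhs
  jac0 <- network$compiled$jac
  rhs <- function(t, y, p) rhs0(time, y, p)
  jac <- function(t, y, p) jac0(time, y, p)
  y <- network$init
  # cumulative-integral bookkeeping states grow without bound; they are
  # excluded from the steady-state criterion and reset to zero at the end
  dyn <- !grepl("^IntRNA_", network$compiled$state_names)

  horizon <- if (method == "root") 200 else 50
  repeat {
    out <- deSolve::lsoda(y, c(0, horizon), rhs, parms,
                          jacfunc = jac, jactype = "fullusr",
                          rtol = 1e-10, atol = 1e-12)
    y <- stats::setNames(out[nrow(out), -1], network$compiled$state_names)
    dy <- rhs(0, y, parms)[[1]][dyn]
    if (max(abs(dy)) < tol || method == "root") break
    if (horizon > t_max) {
      nm <- network$compiled$state_names[dyn]
      stop(sprintf(
        "no steady state within t = %g h; largest residual derivative %.3g (state %s)",
        t_max, max(abs(dy)), nm[which.max(abs(dy))]),
        call. = FALSE)
    }
    horizon <- horizon * 10
  }

  if (method == "root") {
    # damped Newton with Moore-Penrose pseudoinverse (the Jacobian is
    # singular along the conserved STAT3 direction); the cumulative states
    # are excluded from the solve
    idx <- which(dyn)
    for (it in 1:50) {
      f <- rhs(0, y, parms)[[1]][idx]
      if (max(abs(f)) < tol) break
      J <- jac(0, y, parms)[idx, idx, drop = FALSE]
      sv <- svd(J)
      pos <- sv$d > max(sv$d) * 1e-12
      step <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], f)) / sv$d[pos])
      ynew <- y[idx] - as.numeric(step)
      ynew[ynew < 0] <- 0
      y[idx] <- ynew
    }
    f <- rhs(0, y, parms)[[1]][idx]
    if (max(abs(f)) >= tol) {
      nm <- network$compiled$state_names[idx]
      stop(sprintf(
        "root solve did not converge; largest residual derivative %.3g (state %s)",
        max(abs(f)), nm[which.max(abs(f))]),
        call. = FALSE)
    }
  }
  y[!dyn] <- 0
  y
}

# apply one event to (state, inputs)
.apply_event <- function(ev, y, inputs) {
  if (ev$channel == "Ruxolitinib") {
    y["Rux"] <- y[["Rux"]] + ev$amount
  } else if (ev$mode == "wash") {
    inputs["IL6"] <- 0
  } else {
    inputs[ev$channel] <- ev$amount
  }
  list(y = y, inputs = inputs)
}

#' Simulate the model under a protocol
#'
#' Integration restarts at every dose event; between events the inputs are
#' constant and the Ruxolitinib state decays first-order. Observation times
#' and event times are merged into the output grid.
#'
#' @param network a `hep_network`.
#' @param params named parameter values.
#' @param protocol a [protocol()].
#' @param rtol,atol solver tolerances.
#' @param extra_times additional output times (hours).
#' @return object of class `hep_trajectory`: list with `times`, `states`
#'   (time x species matrix, nM), `protocol`, `params`.
#' @export
simulate_protocol <- function(network, params, protocol,
                              rtol = 1e-8, atol = 1e-12,
                              extra_times = NULL) {
  stopifnot(inherits(protocol, "hep_protocol"))
  network <- compile_network(network)
  rhs <- network$compiled$rhs
  jac <- network$compiled$jac
  st <- network$compiled$state_names

  obs_t <- sort(unique(c(protocol$observation_times, extra_times)))
  ev <- protocol$events
  t0 <- min(c(0, obs_t, ev$time))
  t_end <- max(c(obs_t, ev$time, 0))

  if (protocol$pre_equilibrate) {
    y <- equilibrate(network, params)
  } else {
    y <- network$init
  }
  inputs <- .default_inputs()

  # breakpoints: start, each event time, end
  breaks <- sort(unique(c(t0, ev$time, t_end)))
  times_all <- numeric(0)
  states_all <- NULL

  for (k in seq_along(breaks)) {
    tk <- breaks[k]
    # apply events scheduled at tk
    here <- which(ev$time == tk)
    for (i in here) {
      upd <- .apply_event(ev[i, ], y, inputs)
      y <- upd$y; inputs <- upd$inputs
    }
    if (k == length(breaks)) {
      # record final point if requested
      if (tk %in% obs_t && !(length(times_all) && tk == times_all[length(times_all)])) {
        times_all <- c(times_all, tk)
        states_all <- rbind(states_all, y)
      }
      break
    }
    tnext <- breaks[k + 1]
    seg_t <- sort(unique(c(tk, obs_t[obs_t >= tk & obs_t <= tnext], tnext)))
    parms <- .ode_parms(params, inputs)
    out <- deSolve::lsoda(y, seg_t, rhs, parms,
                          jacfunc = jac, jactype = "fullusr",
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      stop(sprintf("stiff-solver failure in segment [%g, %g]; last successful time %g",
                   tk, tnext, max(out[, 1])), call. = FALSE)
    }
    y <- stats::setNames(out[nrow(out), -1], st)
    keep <- out[, 1] < tnext  # right endpoint belongs to next segment
    # keep observation points (and the segment start if observed)
    keep <- keep & (out[, 1] %in% obs_t | out[, 1] == tk)
    keep_obs <- out[, 1] %in% obs_t & out[, 1] < tnext
    if (any(keep_obs)) {
      times_all <- c(times_all, out[keep_obs, 1])
      states_all <- rbind(states_all, out[keep_obs, -1, drop = FALSE])
    }
  }
  # final time point
  if (t_end %in% obs_t && !(length(times_all) && times_all[length(times_all)] == t_end)) {
    times_all <- c(times_all, t_end)
    states_all <- rbind(states_all, y)
  }
  colnames(states_all) <- st
  rownames(states_all) <- NULL
  structure(
    list(times = times_all, states = states_all,
         protocol = protocol, params = params,
         compartments = network$compartments),
    class = "hep_trajectory"
  )
}

#' Interpolate trajectory states at arbitrary times
#' @param traj a `hep_trajectory`.
#' @param t times within the trajectory span.
#' @return matrix (length(t) x species).
#' @export
trajectory_states <- function(traj, t) {
  if (any(t < min(traj$times) - 1e-9 | t > max(traj$times) + 1e-9)) {
    stop("time outside trajectory span", call. = FALSE)
  }
  if (length(traj$times) == 1) {
    out <- traj$states[rep(1, length(t)), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  out <- sapply(colnames(traj$states), function(s) {
    stats::approx(traj$times, traj$states[, s], xout = t, rule = 2)$y
  })
  if (length(t) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(NULL, colnames(traj$states)))
  out
}

#' Closed-form Ruxolitinib concentration profile
#'
#' Sum of decaying exponentials for a dosing schedule:
#' C(t) = sum_i D_i exp(-k (t - t_i)) for t >= t_i.
#'
#' @param schedule a [rux_schedule()] (or list with `times`, `doses`).
#' @param k_rux_deg decay rate (1/h).
#' @return function of time (vectorized).
#' @export
inhibitor_profile <- function(schedule, k_rux_deg) {
  if (any(schedule$doses < 0)) stop("negative dose", call. = FALSE)
  times <- schedule$times
  doses <- schedule$doses
  function(t) {
    vapply(t, function(tt) {
      active <- tt >= times
      sum(doses[active] * exp(-k_rux_deg * (tt - times[active])))
    }, numeric(1))
  }
}
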