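# Maximum-likelihood calibration: -2 log-likelihood objective with
# analytically profiled gel scales and error sigmas, Latin-hypercube
# multi-start optimization in log10 parameter space, profile-likelihood
# identifiability, and monotone control-drift interpolation.

#' Fit a monotone control drift to untreated control measurements
#'
#' Control expression of some genes changes slowly over time in culture; the
#' drift multiplies the gene's basal transcription rate. The interpolant is
#' a monotone piecewise-cubic (Fritsch-Carlson) spline through isotonic knot
#' values, normalized to 1 at the first knot, and clamped to the knot range
#' outside it.
#'
#' @param times control measurement times (hours), >= 2 distinct values.
#' @param values measured control levels (replicates allowed: same time may
#'   repeat).
#' @return list with `fun` (function of time), `knot_times`, `knot_values`
#'   (normalized), `direction` ("increasing", "decreasing" or "constant").
#' @export
fit_control_drift <- function(times, values) {
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("non-finite control data", call. = FALSE)
  }
  agg <- tapply(values, times, mean)
  kt <- as.numeric(names(agg))
  kv <- as.numeric(agg)
  o <- order(kt); kt <- kt[o]; kv <- kv[o]
  if (length(kt) < 2) stop("need >= 2 control time points", call. = FALSE)

  slope <- stats::coef(stats::lm(kv ~ kt))[2]
  if (max(kv) - min(kv) < 1e-12 * max(abs(kv), 1)) {
    direction <- "constant"
    fitted <- rep(kv[1], length(kv))
  } else if (slope >= 0) {
    direction <- "increasing"
    fitted <- stats::isoreg(kt, kv)$yf
  } else {
    direction <- "decreasing"
    fitted <- -stats::isoreg(kt, -kv)$yf
  }
  norm <- fitted / fitted[1]
  if (direction == "constant" || max(norm) - min(norm) < 1e-12) {
    fun <- function(t) rep(1, length(t))
    norm <- rep(1, length(kt))
  } else {
    sp <- stats::splinefun(kt, norm, method = "monoH.FC")
    lo <- kt[1]; hi <- kt[length(kt)]
    fun <- function(t) sp(pmin(pmax(t, lo), hi))
  }
  list(fun = fun, knot_times = kt, knot_values = norm, direction = direction)
}

#' Assemble a calibration problem
#'
#' Bundles the model, the experimental protocols, the observable
#' definitions, the measurement table and the choice of free parameters into
#' one object consumed by [objective_value()], [fit_params()] and
#' [profile_likelihood()].
#'
#' @param network a `hep_network` (ignored if `simulator` is supplied).
#' @param base_params full named parameter vector; free parameters are
#'   overwritten during fitting, the rest stay fixed.
#' @param free names of the free (fitted) dynamic parameters.
#' @param protocols named list of [protocol()]s keyed by experiment label.
#' @param observables named list of [observable()]s keyed by observable
#'   name.
#' @param data measurement table: data.frame with columns experiment,
#'   observable, time_h, replicate, value and optionally gel_id (defaults to
#'   the experiment label); one row per measured value.
#' @param sigma named per-class error sd on the transformed scale, or NULL
#'   to profile sigmas analytically (maximum-likelihood estimate per class).
#' @param lower,upper parameter bounds in natural units (scalars or named
#'   vectors over `free`).
#' @param simulator optional replacement simulator:
#'   function(params, experiment, times) returning a trajectory-like list
#'   (times, states, compartments). Used for the fast gene-module path.
#' @return object of class `hep_problem`.
#' @export
fit_problem <- function(network = NULL, base_params, free, protocols,
                        observables, data, sigma = NULL,
                        lower = 1e-5, upper = 1e5, simulator = NULL) {
  stopifnot(all(free %in% names(base_params)))
  req <- c("experiment", "observable", "time_h", "value")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(data$gel_id)) data$gel_id <- data$experiment
  bad_exp <- setdiff(unique(data$experiment), names(protocols))
  if (length(bad_exp)) {
    stop("data reference unknown experiment(s): ",
         paste(bad_exp, collapse = ", "), call. = FALSE)
  }
  bad_obs <- setdiff(unique(data$observable), names(observables))
  if (length(bad_obs)) {
    stop("data reference unknown observable(s): ",
         paste(bad_obs, collapse = ", "), call. = FALSE)
  }
  if (!is.null(network)) network <- compile_network(network)
  expand <- function(b) {
    if (length(b) == 1) stats::setNames(rep(b, length(free)), free)
    else b[free]
  }
  exp_times <- lapply(split(data$time_h, data$experiment),
                      function(tt) sort(unique(tt)))
  structure(
    list(network = network, base_params = base_params, free = free,
         protocols = protocols, observables = observables, data = data,
         sigma = sigma, lower = expand(lower), upper = expand(upper),
         simulator = simulator, exp_times = exp_times),
    class = "hep_problem"
  )
}

# simulate all experiments needed by the data at the given parameters
.simulate_all <- function(problem, params) {
  out <- list()
  for (ex in names(problem$exp_times)) {
    tt <- problem$exp_times[[ex]]
    if (!is.null(problem$simulator)) {
      out[[ex]] <- problem$simulator(params, ex, tt)
    } else {
      pr <- problem$protocols[[ex]]
      pr$observation_times <- sort(unique(c(pr$observation_times, tt)))
      out[[ex]] <- simulate_protocol(problem$network, params, pr)
    }
  }
  out
}

#' Evaluate the -2 log-likelihood objective
#'
#' Gaussian error on the transformed scale:
#' sum over records of (data - pred)^2 / sigma^2 + log(2 pi sigma^2).
#' Free per-gel scales (and the log-scale shift for log10 observables) are
#' profiled analytically; sigmas are profiled per error-model class unless
#' fixed in the problem.
#'
#' @param problem a [fit_problem()].
#' @param par named values for (a subset of) the free parameters, natural
#'   scale; defaults to the base parameters.
#' @param details if TRUE, also return residuals, profiled scales and
#'   sigmas.
#' @return -2 log-likelihood (numeric), or a list when `details`.
#' @export
objective_value <- function(problem, par = NULL, details = FALSE) {
  params <- problem$base_params
  if (!is.null(par)) params[names(par)] <- par
  sims <- .simulate_all(problem, params)

  d <- problem$data
  key <- paste(d$observable, d$gel_id, sep = "\r")
  resid <- numeric(nrow(d))
  classes <- character(nrow(d))
  scales <- list()
  for (grp in unique(key)) {
    idx <- which(key == grp)
    obs <- problem$observables[[d$observable[idx[1]]]]
    classes[idx] <- obs$class
    pred <- numeric(length(idx))
    for (ex in unique(d$experiment[idx])) {
      sel <- idx[d$experiment[idx] == ex]
      st <- trajectory_states(sims[[ex]], d$time_h[sel])
      pred[match(sel, idx)] <- .observable_raw(st, obs, sims[[ex]]$compartments)
    }
    val <- d$value[idx]
    if (obs$absolute) {
      p_t <- if (obs$transform == "log10") log10(pred) else pred
      resid[idx] <- val - p_t
      scales[[grp]] <- 1
    } else if (obs$transform == "log10") {
      if (any(pred <= 0)) {
        stop(sprintf("log10 of non-positive prediction for %s at t = %g h",
                     obs$name, d$time_h[idx][pred <= 0][1]), call. = FALSE)
      }
      lp <- log10(pred)
      shift <- mean(val - lp)         # profiled log10 scale
      resid[idx] <- val - lp - shift
      scales[[grp]] <- 10^shift
    } else {
      s <- sum(val * pred) / sum(pred^2)   # profiled linear scale
      if (!is.finite(s)) s <- 1
      resid[idx] <- val - s * pred
      scales[[grp]] <- s
    }
  }
  if (any(!is.finite(resid))) return(if (details) list(objective = Inf) else Inf)

  nll2 <- 0
  sigmas <- c()
  for (cl in unique(classes)) {
    r <- resid[classes == cl]
    s <- if (!is.null(problem$sigma)) problem$sigma[[cl]] else
      sqrt(mean(r^2))
    s <- max(s, 1e-12)
    nll2 <- nll2 + sum(r^2 / s^2 + log(2 * pi * s^2))
    sigmas[cl] <- s
  }
  if (details) {
    list(objective = nll2, residuals = resid, scales = scales,
         sigmas = sigmas, params = params)
  } else nll2
}

#' Maximum-likelihood fit by Latin-hypercube multi-start
#'
#' Free parameters are searched in log10 space within the problem bounds,
#' starting from a Latin-hypercube design with a fixed seed; each start is
#' refined by L-BFGS-B. The per-start results (the "waterfall") are
#' returned sorted by final objective. Re-running with the same seed
#' reproduces the fit exactly.
#'
#' @param problem a [fit_problem()].
#' @param n_starts number of starts.
#' @param seed RNG seed for the start design.
#' @param include_base also start from the problem's base parameters.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return object of class `hep_fit`: best parameters (natural scale),
#'   objective, per-start table, seed.
#' @export
fit_params <- function(problem, n_starts = 10, seed = 1,
                       include_base = FALSE, maxit = 200) {
  free <- problem$free
  lo <- log10(problem$lower); up <- log10(problem$upper)
  # seed the start design without clobbering the caller's RNG stream
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  lh <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(lh, 2, up - lo, "*"), 2, lo, "+")
  if (include_base) {
    starts <- rbind(log10(problem$base_params[free]), starts)
  }
  fn <- function(x) {
    objective_value(problem, stats::setNames(10^x, free))
  }
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                   lower = lo, upper = up,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    runs[[i]] <- if (is.null(res)) {
      list(par = starts[i, ], value = Inf, converged = FALSE)
    } else {
      list(par = res$par, value = res$value,
           converged = res$convergence == 0)
    }
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) stop("all starts failed", call. = FALSE)
  o <- order(values)
  waterfall <- data.frame(
    start = o,
    objective = values[o],
    converged = vapply(runs, `[[`, logical(1), "converged")[o]
  )
  best <- runs[[o[1]]]
  structure(
    list(par = stats::setNames(10^best$par, free),
         objective = best$value,
         waterfall = waterfall,
         starts = starts,
         problem = problem,
         seed = seed),
    class = "hep_fit"
  )
}

#' @export
print.hep_fit <- function(x, ...) {
  cat(sprintf("ML fit: -2logL = %.4f over %d starts (seed %d)\n",
              x$objective, nrow(x$waterfall), x$seed))
  print(round(x$par, 6))
  invisible(x)
}

#' Two-stage fit: core model
#'
#' Thin wrapper over [fit_params()] for the core-stage problem (datasets
#' covering the signalling observables, including inhibitor conditions).
#'
#' @inheritParams fit_params
#' @return `hep_fit`.
#' @export
fit_core <- function(problem, n_starts = 50, seed = 1, ...) {
  fit_params(problem, n_starts = n_starts, seed = seed, ...)
}

#' Fast gene-module simulator given a frozen core
#'
#' With the core fixed, each gene module is a small linear system forced by
#' the core pSTAT3 trajectory; this builds a simulator that integrates only
#' the gene states against an interpolated pSTAT3 forcing, orders of
#' magnitude faster than the full network.
#'
#' @param network full network (for compartment volumes and the gene
#'   definition).
#' @param core_params core parameter values (fixed).
#' @param gene gene name.
#' @param protocols named protocol list (IL-6 / ActD experiments; the core
#'   trajectory per protocol is cached on first use).
#' @param drift_fun control drift (default constant 1).
#' @return function(params, experiment, times) -> trajectory-like list.
#' @export
gene_simulator <- function(network, core_params, gene, protocols,
                           drift_fun = NULL) {
  stopifnot(gene %in% app_genes())
  delayed <- gene %in% delayed_genes()
  Vc <- network$compartments$cytoplasm$volume_pl
  Vn <- network$compartments$nucleus$volume_pl
  n2c <- Vn / Vc
  if (is.null(drift_fun)) drift_fun <- function(t) rep(1, length(t))
  gobj <- network$genes[[gene]]
  hill <- if (!is.null(gobj)) gobj$txn_hill else 1
  cache <- new.env(parent = emptyenv())

  core_net <- build_core_model(core_params[core_parameter_names()],
                               network$compartments, network$fixed_totals)
  core_net <- compile_network(core_net)

  get_core <- function(ex) {
    if (!is.null(cache[[ex]])) return(cache[[ex]])
    pr <- protocols[[ex]]
    t_hi <- max(pr$observation_times, pr$events$time, 1)
    dense <- sort(unique(c(pr$events$time, seq(min(c(0, pr$events$time)),
                                               t_hi, length.out = 600))))
    pr$observation_times <- dense
    tr <- simulate_protocol(core_net, core_params, pr)
    actd_ev <- pr$events[pr$events$channel == "ActD" & pr$events$amount > 0, ]
    actd_from <- if (nrow(actd_ev)) min(actd_ev$time) else Inf
    res <- list(
      ps_fun = stats::approxfun(tr$times, tr$states[, "pSTAT3"], rule = 2),
      actd_from = actd_from, t0 = min(tr$times))
    cache[[ex]] <- res
    res
  }

  pn <- gene_parameter_names(gene)
  function(params, experiment, times) {
    core <- get_core(experiment)
    k_txn <- params[[paste0("k_txn_", gene)]]
    k_bas <- params[[paste0("k_txn_basal_", gene)]]
    k_deg <- params[[paste0("k_mrna_deg_", gene)]]
    tau <- if (delayed) params[[paste0("tau_", gene)]] else NULL
    nst <- if (delayed) 6L else 1L
    rhs <- function(t, y, parms) {
      gate <- if (t >= core$actd_from) 0 else 1
      txn <- (k_bas * drift_fun(t) + k_txn * core$ps_fun(t)^hill) * gate
      if (delayed) {
        r <- 5 / tau
        dy <- c(txn - r * y[1],
                r * (y[1:4] - y[2:5]),
                r * y[5] * n2c - k_deg * y[6])
      } else {
        dy <- txn - k_deg * y[1]
      }
      list(dy)
    }
    # steady state under the total pre-stimulation transcription flux
    # (basal term at the initial drift plus the resting-pSTAT3 term)
    txn0 <- k_bas * drift_fun(core$t0) + k_txn * core$ps_fun(core$t0)^hill
    y0 <- if (delayed) {
      chain <- rep(txn0 / (5 / tau), 5)
      c(chain, txn0 * n2c / k_deg)
    } else txn0 / k_deg
    tt <- sort(unique(c(core$t0, times)))
    out <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-8, atol = 1e-12,
                          maxsteps = 50000)
    mrna <- out[match(times, out[, 1]), nst + 1]
    states <- matrix(mrna, ncol = 1,
                     dimnames = list(NULL, paste0("AppRNA_", gene)))
    list(times = times, states = states,
         compartments = network$compartments)
  }
}

#' Two-stage fit: per-gene downstream modules with the core frozen
#'
#' Fits each gene module independently on its own measurements, holding the
#' core parameters fixed at the supplied values (gene modules never feed
#' back into the core).
#'
#' @param network full network (core + genes).
#' @param core_params fixed core parameter vector.
#' @param base_params full parameter vector supplying gene starting values.
#' @param protocols named protocol list.
#' @param observables observable definitions.
#' @param data measurement table (gene qPCR records).
#' @param genes genes to fit (default: all with data).
#' @param n_starts,seed,lower,upper,sigma as in [fit_params()].
#' @param drifts optional named list of control-drift functions per gene.
#' @return named list of `hep_fit`, one per gene.
#' @export
fit_genes <- function(network, core_params, base_params, protocols,
                      observables, data, genes = NULL,
                      n_starts = 5, seed = 1, sigma = NULL,
                      lower = 1e-5, upper = 1e5, drifts = list()) {
  obs_gene <- vapply(names(observables), function(on) {
    f <- observables[[on]]$formula
    if (is.character(f)) return(NA_character_)
    sp <- names(f)[1]
    if (grepl("^AppRNA_", sp)) sub("^AppRNA_", "", sp) else NA_character_
  }, character(1))
  if (is.null(genes)) {
    genes <- unique(stats::na.omit(obs_gene[unique(data$observable)]))
  }
  fits <- list()
  for (g in genes) {
    keep <- data$observable %in% names(obs_gene)[!is.na(obs_gene) &
                                                   obs_gene == g]
    dg <- data[keep, , drop = FALSE]
    if (!nrow(dg)) next
    sim <- gene_simulator(network, core_params, g, protocols,
                          drift_fun = drifts[[g]])
    prob <- fit_problem(
      network = NULL, base_params = base_params,
      free = gene_parameter_names(g),
      protocols = protocols, observables = observables, data = dg,
      sigma = sigma, lower = lower, upper = upper, simulator = sim)
    fits[[g]] <- fit_params(prob, n_starts = n_starts, seed = seed)
  }
  fits
}

#' Profile likelihood for one parameter
#'
#' Fixes the parameter on a grid of values and re-optimizes all remaining
#' free parameters at each grid point (warm-started from the fit optimum).
#' 95% pointwise confidence bounds are the crossings of
#' best objective + 3.84 (chi-square, 1 df), refined by bisection. The scan
#' starts on a grid of half-width `span` around the fitted value and extends
#' outward automatically until the threshold is crossed on both sides of the
#' profile minimum or the parameter bounds are reached; a bound not crossed
#' before the parameter bounds is flagged open (practical
#' non-identifiability).
#'
#' @param problem the `hep_problem` used for the fit.
#' @param fit the `hep_fit` to profile around.
#' @param param name of the profiled parameter.
#' @param span half-width of the scan in log10 units (default 1.5).
#' @param n_grid grid size (default 11, symmetric around the optimum).
#' @param threshold objective increase defining the confidence bound
#'   (default 3.84).
#' @param maxit re-optimization iteration cap.
#' @return object of class `hep_profile`: data.frame grid (value,
#'   objective, converged) plus `lower`, `upper`, `lower_open`,
#'   `upper_open`, `threshold`.
#' @export
profile_likelihood <- function(problem, fit, param, span = 1.5,
                               n_grid = 11, threshold = 3.84, maxit = 100) {
  stopifnot(param %in% problem$free)
  others <- setdiff(problem$free, param)
  p_hat <- log10(fit$par[[param]])
  grid <- seq(p_hat - span, p_hat + span, length.out = n_grid)
  lo <- log10(problem$lower); up <- log10(problem$upper)
  grid <- pmin(pmax(grid, lo[[param]]), up[[param]])
  grid <- sort(unique(c(grid, p_hat)))

  x_warm <- log10(fit$par[others])
  prof <- data.frame(value = 10^grid, objective = NA_real_,
                     converged = NA)
  for (i in order(abs(grid - p_hat))) {    # scan outward from the optimum
    fixed <- stats::setNames(10^grid[i], param)
    if (length(others)) {
      fn <- function(x) {
        objective_value(problem,
                        c(fixed, stats::setNames(10^x, others)))
      }
      res <- tryCatch(
        stats::optim(x_warm, fn, method = "L-BFGS-B",
                     lower = lo[others], upper = up[others],
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (is.null(res)) {
        prof$objective[i] <- Inf; prof$converged[i] <- FALSE
      } else {
        prof$objective[i] <- res$value
        prof$converged[i] <- res$convergence == 0
        if (grid[i] == p_hat) x_warm <- res$par
      }
    } else {
      prof$objective[i] <- objective_value(problem, fixed)
      prof$converged[i] <- TRUE
    }
  }
  x_hat <- log10(fit$par[others])
  prof_obj <- function(v) {
    fixed <- stats::setNames(v, param)
    if (!length(others)) return(objective_value(problem, fixed))
    res <- tryCatch(
      stats::optim(x_hat, function(x) {
        objective_value(problem, c(fixed, stats::setNames(10^x, others)))
      }, method = "L-BFGS-B", lower = lo[others], upper = up[others],
      control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) Inf else res$value
  }

  # extend the scan outward until the objective crosses the threshold on
  # both sides of the profile minimum (or a parameter bound is reached): a
  # fixed span around the fitted value is not enough when the local fit
  # missed the global optimum, in which case the scan walks downhill,
  # re-centres on the better optimum it discovers, and brackets the
  # crossings around that
  step <- if (n_grid > 1) 2 * span / (n_grid - 1) else span
  add_point <- function(v) {
    o <- prof_obj(v)
    prof <<- rbind(prof, data.frame(value = v, objective = o,
                                    converged = is.finite(o)))
    prof <<- prof[order(prof$value), ]
  }
  for (ext in seq_len(4 * n_grid + 60)) {
    best <- min(prof$objective, fit$objective)
    cut <- best + threshold
    i_min <- which.min(prof$objective)
    need_lo <- all(prof$objective[seq_len(i_min)] <= cut)
    need_hi <- all(prof$objective[i_min:nrow(prof)] <= cut)
    v_lo <- log10(prof$value[1]); v_hi <- log10(prof$value[nrow(prof)])
    did <- FALSE
    if (need_lo && v_lo > lo[[param]] + 1e-12) {
      add_point(10^max(v_lo - step, lo[[param]])); did <- TRUE
    }
    if (need_hi && v_hi < up[[param]] - 1e-12) {
      add_point(10^min(v_hi + step, up[[param]])); did <- TRUE
    }
    if (!did) break
  }
  best <- min(prof$objective, fit$objective)
  cut <- best + threshold

  cross <- function(side) {
    # centre on the profile's own minimum: if a scan point beat the fitted
    # optimum, the LR region surrounds that point, not the fitted value
    i_hat <- which.min(prof$objective)
    idx <- if (side == "lower") rev(seq_len(i_hat)) else
      seq(i_hat, nrow(prof))
    run <- prof[idx, ]
    out <- which(run$objective > cut)
    if (!length(out)) return(list(bound = run$value[nrow(run)], open = TRUE))
    j <- out[1]
    # bisect the bracketing grid cell: the grid is coarse and the profile
    # locally quadratic, so interpolating straight across the cell would
    # place the crossing far too close to the optimum
    x_in <- log10(run$value[j - 1]); y_in <- run$objective[j - 1]
    x_out <- log10(run$value[j]); y_out <- run$objective[j]
    for (it in seq_len(10)) {
      if (abs(x_out - x_in) < 2e-3) break
      x_mid <- (x_in + x_out) / 2
      y_mid <- prof_obj(10^x_mid)
      if (y_mid > cut) {
        x_out <- x_mid; y_out <- y_mid
      } else {
        x_in <- x_mid; y_in <- y_mid
      }
    }
    # sqrt(objective rise) is linear in the parameter for a quadratic
    # profile, so interpolate the final sub-cell on that scale
    s_in <- sqrt(max(y_in - best, 0)); s_out <- sqrt(y_out - best)
    s_cut <- sqrt(threshold)
    bound <- x_in + (s_cut - s_in) * (x_out - x_in) /
      max(s_out - s_in, .Machine$double.eps)
    list(bound = 10^bound, open = FALSE)
  }
  lo_b <- cross("lower"); up_b <- cross("upper")
  structure(
    list(param = param, profile = prof, best_objective = best,
         lower = lo_b$bound, upper = up_b$bound,
         lower_open = lo_b$open, upper_open = up_b$open,
         threshold = threshold),
    class = "hep_profile"
  )
}

#' @export
print.hep_profile <- function(x, ...) {
  cat(sprintf("profile for %s: 95%% interval [%.4g%s, %.4g%s]\n",
              x$param, x$lower, if (x$lower_open) " (open)" else "",
              x$upper, if (x$upper_open) " (open)" else ""))
  invisible(x)
}
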