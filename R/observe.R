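# Observation model: maps trajectories to measured quantities with
# per-experiment scale/offset nuisance parameters, linear or log10
# transformation, and absolute (nuisance-free) observables.

#' Define an observable
#'
#' An observable is a linear combination of species concentrations, scaled
#' and offset by nuisance parameters, then optionally log10-transformed.
#' Absolute observables (the mass-spec phospho-degree and the imaging
#' nuc/cyt ratio) carry no nuisance parameters.
#'
#' @param name observable name.
#' @param formula named numeric vector of species coefficients, or one of
#'   the built-ins "phospho_degree", "nuc_cyt_ratio".
#' @param transform "linear" or "log10".
#' @param absolute logical; absolute observables have scale fixed to 1 and
#'   offset 0.
#' @param class error-model class (one sigma is estimated per class), e.g.
#'   "immunoblot", "qpcr_time", "qpcr_dose", "beadarray", "imaging",
#'   "massspec".
#' @return object of class `hep_observable`.
#' @export
observable <- function(name, formula, transform = c("linear", "log10"),
                       absolute = FALSE, class = "default") {
  transform <- match.arg(transform)
  if (is.character(formula)) {
    formula <- match.arg(formula, c("phospho_degree", "nuc_cyt_ratio"))
    absolute <- TRUE
  }
  structure(
    list(name = name, formula = formula, transform = transform,
         absolute = absolute, class = class),
    class = "hep_observable"
  )
}

#' Default observable set for the calibration experiments
#' @param genes gene names to include qPCR observables for.
#' @return named list of observables.
#' @export
default_observables <- function(genes = app_genes()) {
  obs <- list(
    pJAK1  = observable("pJAK1", c(pJAK1_gp130 = 1, pJAK1_pgp130 = 1),
                        class = "immunoblot"),
    pgp130 = observable("pgp130", c(pJAK1_pgp130 = 1), class = "immunoblot"),
    pSTAT3 = observable("pSTAT3", c(pSTAT3 = 1), class = "immunoblot"),
    tSTAT3 = observable("tSTAT3", c(STAT3 = 1, pSTAT3 = 1),
                        class = "immunoblot"),
    SOCS3  = observable("SOCS3", c(SOCS3 = 1), class = "immunoblot"),
    Socs3_mrna = observable("Socs3_mrna", c(Socs3RNA = 1),
                            class = "qpcr_time"),
    Socs3_mrna_dose = observable("Socs3_mrna_dose", c(Socs3RNA = 1),
                                 transform = "log10", class = "qpcr_dose"),
    phospho_degree = observable("phospho_degree", "phospho_degree",
                                class = "massspec"),
    nuc_cyt_ratio = observable("nuc_cyt_ratio", "nuc_cyt_ratio",
                               class = "imaging")
  )
  for (g in genes) {
    obs[[paste0(g, "_mrna")]] <-
      observable(paste0(g, "_mrna"),
                 stats::setNames(1, paste0("AppRNA_", g)),
                 class = "qpcr_time")
    obs[[paste0(g, "_mrna_dose")]] <-
      observable(paste0(g, "_mrna_dose"),
                 stats::setNames(1, paste0("AppRNA_", g)),
                 transform = "log10", class = "qpcr_dose")
  }
  obs
}

# raw (untransformed, unscaled) observable value from a state matrix
.observable_raw <- function(states, obs, compartments) {
  if (is.character(obs$formula)) {
    Vc <- compartments$cytoplasm$volume_pl
    Vn <- compartments$nucleus$volume_pl
    S <- states[, "STAT3"]; pS <- states[, "pSTAT3"]; nS <- states[, "nSTAT3"]
    if (obs$formula == "phospho_degree") {
      return(unname(pS * Vc / ((S + pS) * Vc + nS * Vn)))
    }
    cyt <- S + pS
    if (any(cyt <= 0)) {
      stop("zero cytoplasmic STAT3 in nuc/cyt ratio", call. = FALSE)
    }
    return(unname(nS / cyt))
  }
  miss <- setdiff(names(obs$formula), colnames(states))
  if (length(miss)) {
    stop("observable ", obs$name, " references unknown species: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as.numeric(states[, names(obs$formula), drop = FALSE] %*% obs$formula)
}

#' Predict an observable along a trajectory
#'
#' Applies formula, scale, offset, then the transformation, in that order.
#'
#' @param traj a `hep_trajectory`.
#' @param obs a [observable()].
#' @param times observation times (default: the trajectory's own times).
#' @param scale,offset nuisance parameters (ignored for absolute
#'   observables).
#' @return numeric vector of predictions.
#' @export
predict_observable <- function(traj, obs, times = traj$times,
                               scale = 1, offset = 0) {
  states <- trajectory_states(traj, times)
  raw <- .observable_raw(states, obs, traj$compartments)
  if (obs$absolute) {
    val <- raw
  } else {
    val <- scale * raw + offset
  }
  if (obs$transform == "log10") {
    if (any(val <= 0)) {
      bad <- times[val <= 0][1]
      stop(sprintf("log10 of non-positive prediction for %s at t = %g h",
                   obs$name, bad), call. = FALSE)
    }
    val <- log10(val)
  }
  val
}

#' Degree of STAT3 Tyr-705 phosphorylation
#'
#' Fraction of total cellular STAT3 (amount across both compartments) that
#' is phosphorylated: pSTAT3 * V_cyt / ((STAT3 + pSTAT3) * V_cyt +
#' nSTAT3 * V_nuc). Absolute observable, no nuisance parameters.
#'
#' @param traj a `hep_trajectory`.
#' @param t time (hours).
#' @return fraction in \[0, 1\].
#' @export
phospho_degree <- function(traj, t) {
  states <- trajectory_states(traj, t)
  .observable_raw(states, observable("pd", "phospho_degree"),
                  traj$compartments)
}

#' Nuclear-to-cytoplasmic STAT3 concentration ratio
#'
#' nSTAT3 / (STAT3 + pSTAT3), concentrations per compartment; the live-cell
#' imaging observable.
#'
#' @inheritParams phospho_degree
#' @return ratio.
#' @export
nuc_cyt_ratio <- function(traj, t) {
  states <- trajectory_states(traj, t)
  .observable_raw(states, observable("nc", "nuc_cyt_ratio"),
                  traj$compartments)
}
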