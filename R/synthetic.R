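# Synthetic-data generation: emulates every measurement class used for
# calibration and validation (immunoblot time courses with per-gel scales,
# qPCR time courses and dose responses, inhibitor experiments, mass-spec
# phospho-degree, live-cell imaging ratios, in-vivo serum IL-6 and liver
# bead-array signals, ex-vivo dose-response calibration curves) from the
# committed reference parameterization.

#' Default experimental protocols of the calibration suite
#'
#' Time courses at 40 ng/mL IL-6 (signalling to 2 h, genes to 48 h), qPCR
#' dose responses over 0.1-500 ng/mL read at 1/6/24 h, Ruxolitinib 500 nM
#' pre-treatment at -1 h, Stattic 5 uM co-treatment observed for at most
#' 2 h, a 30-min IL-6 pulse with wash, and imaging/mass-spec protocols.
#'
#' @param doses dose-response IL-6 grid (ng/mL).
#' @return named list of [protocol()]s.
#' @export
suite_protocols <- function(doses = c(0.1, 0.5, 1, 2.5, 5, 10, 25, 50,
                                      100, 250, 500)) {
  tc_min <- c(0, 10, 20, 30, 40, 60, 90, 120) / 60
  gene_h <- c(0, 1, 3, 6, 12, 24, 48)
  pr <- list(
    tc40 = stimulation_protocol(40, tc_min, label = "tc40"),
    genes40 = stimulation_protocol(40, gene_h, label = "genes40"),
    rux_pre = protocol(rbind(dose_event(-1, "Ruxolitinib", 500, "add"),
                             dose_event(0, "IL6", 40, "set")),
                       tc_min, label = "rux_pre"),
    stattic_pre = protocol(rbind(dose_event(-1, "Stattic", 5000, "set"),
                                 dose_event(0, "IL6", 40, "set")),
                           tc_min[tc_min <= 1], label = "stattic_pre"),
    pulse30 = protocol(rbind(dose_event(0, "IL6", 40, "set"),
                             dose_event(0.5, "IL6", 0, "wash")),
                       tc_min, label = "pulse30"),
    massspec40 = stimulation_protocol(40, 18 / 60, label = "massspec40"),
    imaging500 = stimulation_protocol(500, c(0, 25 / 60),
                                      label = "imaging500")
  )
  for (d in doses) {
    lab <- sprintf("dose_%g", d)
    pr[[lab]] <- stimulation_protocol(d, c(1, 6, 24), label = lab)
  }
  pr
}

# lognormal with mean `m` and coefficient of variation `cv`
.rlnorm_mean_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the synthetic calibration suite
#'
#' Simulates every suite protocol at the reference parameters, applies one
#' log-normal scale factor per gel/experiment group to the non-absolute
#' observables (immunoblot and qPCR data are relative), and adds Gaussian
#' noise with the per-class sd on the transformed scale. The same seed
#' always yields the identical table.
#'
#' @param ref a `hep_reference`.
#' @param noise named per-class sd (default `ref$noise`); use 0 for
#'   noise-free output.
#' @param seed RNG seed.
#' @param replicates replicates per record (default 2, as in the qPCR
#'   experiments).
#' @param network optional pre-built reference network.
#' @return data.frame: experiment, observable, time_h, replicate, value,
#'   gel_id.
#' @export
generate_suite <- function(ref = reference_parameters(), noise = ref$noise,
                           seed = 1, replicates = 2, network = NULL) {
  if (is.null(network)) network <- build_reference_network(ref)
  params <- reference_param_vector(ref)
  protocols <- suite_protocols()
  obs <- default_observables()
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  # measurement plan: which observables are read in which experiment
  plan <- list(
    tc40 = c("pJAK1", "pgp130", "pSTAT3", "tSTAT3", "SOCS3", "Socs3_mrna"),
    genes40 = paste0(app_genes(), "_mrna"),
    rux_pre = c("pSTAT3", "Socs3_mrna"),
    stattic_pre = c("pSTAT3"),
    pulse30 = c("pSTAT3"),
    massspec40 = c("phospho_degree"),
    imaging500 = c("nuc_cyt_ratio")
  )
  dose_labels <- grep("^dose_", names(protocols), value = TRUE)
  for (lab in dose_labels) {
    plan[[lab]] <- c("Socs3_mrna_dose", paste0(app_genes(), "_mrna_dose"))
  }

  rows <- list()
  for (ex in names(plan)) {
    pr <- protocols[[ex]]
    tr <- simulate_protocol(network, params, pr)
    for (on in plan[[ex]]) {
      ob <- obs[[on]]
      tt <- pr$observation_times
      raw <- predict_observable(tr, ob, tt, scale = 1, offset = 0)
      # undo the transform: noise and scaling are applied explicitly below
      if (ob$transform == "log10") raw <- 10^raw
      gel <- paste(ex, on, sep = ":")
      if (ob$absolute) {
        s <- 1
      } else {
        # per-gel scale: lognormal around 1 / mean(signal), so measured
        # arbitrary units are O(1)
        s <- stats::rlnorm(1, 0, ref$gel_scale_sdlog) / mean(raw[raw > 0])
      }
      sd_cl <- if (length(noise)) unname(noise[ob$class]) else 0
      if (is.na(sd_cl)) sd_cl <- 0
      for (r in seq_len(replicates)) {
        mval <- if (ob$absolute) raw else s * raw
        if (ob$transform == "log10") {
          val <- log10(mval) + stats::rnorm(length(mval), 0, sd_cl)
        } else {
          val <- mval + stats::rnorm(length(mval), 0, sd_cl)
        }
        rows[[length(rows) + 1]] <- data.frame(
          experiment = ex, observable = on, time_h = tt,
          replicate = r, value = val, gel_id = gel,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the ex-vivo IL-6 to phospho-STAT3 calibration curve
#'
#' Bead-array signals of the reference 4-parameter logistic curve at a dose
#' grid, with additive Gaussian noise.
#'
#' @param ref a `hep_reference`.
#' @param doses IL-6 dose grid (ng/mL).
#' @param replicates replicates per dose.
#' @param seed RNG seed.
#' @param noise_sd signal sd (default: the bead-array class sd).
#' @return data.frame: dose, replicate, signal.
#' @export
generate_exvivo_curve <- function(ref = reference_parameters(),
                                  doses = c(0.1, 0.5, 1, 2.5, 5, 10, 25,
                                            50, 100, 250, 500),
                                  replicates = 3, seed = 1,
                                  noise_sd = unname(ref$noise["beadarray"])) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  h <- ref$hill
  rows <- expand.grid(dose = doses, replicate = seq_len(replicates))
  mu <- hill4(rows$dose, h[["y_min"]], h[["y_max"]], h[["ec50"]],
              h[["hill"]])
  rows$signal <- mu + stats::rnorm(nrow(rows), 0, noise_sd)
  rows
}

# smooth pulse shape: 1 at the peak time, gamma-density-like rise and fall
.pulse_shape <- function(t, peak_time = 2, shape = 2) {
  ifelse(t <= 0, 0, (t / peak_time)^shape * exp(shape * (1 - t / peak_time)))
}

#' Generate synthetic in-vivo serum IL-6 and liver phospho-STAT3 data
#'
#' Serum IL-6 per condition follows a pulse peaking at 2 h (log-normal
#' replicate noise with the condition's coefficient of variation; the
#' sample mean at the peak matches the configured peak mean). Liver
#' phospho-STAT3 signals are obtained by pushing the condition's
#' local-equivalent IL-6 pulse (peaking at 1 h for LPS, 2 h for PHx)
#' through the reference ex-vivo 4PL curve, plus Gaussian noise.
#'
#' @param ref a `hep_reference`.
#' @param conditions subset of c("PHx", "LPS", "Sham", "NaCl").
#' @param n replicates (animals) per time point.
#' @param seed RNG seed.
#' @param times serum sampling times (hours).
#' @return list with `serum` and `liver` data.frames (condition, time_h,
#'   replicate, value).
#' @export
generate_invivo <- function(ref = reference_parameters(),
                            conditions = c("PHx", "LPS", "Sham", "NaCl"),
                            n = 5, seed = 1,
                            times = c(0, 1, 2, 4, 8, 24)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  bad <- setdiff(conditions, c("PHx", "LPS", "Sham", "NaCl"))
  if (length(bad)) stop("invalid condition: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  iv <- ref$invivo
  base <- iv$baseline
  serum <- list(); liver <- list()
  for (cond in conditions) {
    sp <- iv[[cond]]
    cv <- sp$peak_sd / sp$peak_mean
    for (tt in times) {
      m <- base + (sp$peak_mean - base) * .pulse_shape(tt, iv$peak_time)
      vals <- .rlnorm_mean_cv(n, m, cv)
      serum[[length(serum) + 1]] <- data.frame(
        condition = cond, time_h = tt, replicate = seq_len(n), value = vals)
    }
    if (!is.null(sp$local)) {
      h <- ref$hill
      local_mid <- mean(sp$local)
      liver_peak <- if (cond == "LPS") 1 else 2
      for (tt in times) {
        il6_local <- local_mid * .pulse_shape(tt, liver_peak)
        mu <- hill4(il6_local, h[["y_min"]], h[["y_max"]], h[["ec50"]],
                    h[["hill"]])
        vals <- mu + stats::rnorm(n, 0, unname(ref$noise["beadarray"]))
        liver[[length(liver) + 1]] <- data.frame(
          condition = cond, time_h = tt, replicate = seq_len(n),
          value = vals)
      }
    }
  }
  list(serum = do.call(rbind, serum),
       liver = if (length(liver)) do.call(rbind, liver) else NULL)
}
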