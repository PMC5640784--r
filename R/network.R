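# Avogadro's number (1/mol); used for molecule-count <-> nM conversion.
.AVOGADRO <- 6.02214076e23

#' Hepatocyte compartments
#'
#' The two compartments of the model: cytoplasm and nucleus of a (frequently
#' binucleated) primary mouse hepatocyte, with volumes 12.67 and 0.5 pL.
#'
#' @param cytoplasm_pl,nucleus_pl compartment volumes in picoliters.
#' @return named list of compartments, each with `name` and `volume_pl`.
#' @export
hep_compartments <- function(cytoplasm_pl = 12.67, nucleus_pl = 0.5) {
  if (!is.numeric(cytoplasm_pl) || cytoplasm_pl <= 0 ||
      !is.numeric(nucleus_pl) || nucleus_pl <= 0) {
    stop("compartment volumes must be positive", call. = FALSE)
  }
  list(
    cytoplasm = list(name = "cytoplasm", volume_pl = cytoplasm_pl),
    nucleus   = list(name = "nucleus",   volume_pl = nucleus_pl)
  )
}

#' Names of the 22 dynamic core parameters
#'
#' Rate constants, the Socs3 transcriptional delay and the inhibition
#' constants of the core receptor/STAT3/SOCS3 model. All are strictly
#' positive; time unit is hours, concentrations nM (IL-6 in ng/mL).
#'
#' @return character vector of length 22.
#' @export
core_parameter_names <- function() {
  c("k_rec_syn", "k_rec_deg", "k_socs3_recdeg",
    "k_jak_act_basal", "k_jak_act_il6", "k_gp130_phos",
    "k_deact1", "k_deact2",
    "k_stat3_act", "Ki_socs3",
    "k_stat3_imp", "k_pstat3_imp", "k_stat3_exp",
    "k_socs3_txn", "k_socs3_txn_basal", "tau_socs3",
    "k_socs3_mrna_deg", "k_socs3_trl", "k_socs3_deg",
    "Ki_rux", "k_rux_deg", "Ki_stattic")
}

#' The seven modelled acute-phase-protein genes
#' @return character vector.
#' @export
app_genes <- function() {
  c("Cxcl10", "Fgg", "Hamp", "Il33", "Apcs", "Hp", "Hpx")
}

#' Genes whose transcription carries an explicit delay chain
#' @return character vector (Apcs and Hamp are excluded).
#' @export
delayed_genes <- function() setdiff(app_genes(), c("Apcs", "Hamp"))

#' Convert molecule counts to nanomolar concentration (and back)
#'
#' `convert_units` maps molecules per cell in a compartment to nM;
#' `convert_units_inverse` is the exact inverse.
#'
#' @param count molecules per cell (>= 0).
#' @param compartment a compartment from [hep_compartments()].
#' @return concentration in nM.
#' @export
convert_units <- function(count, compartment) {
  if (is.null(compartment$volume_pl)) stop("unknown compartment", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  # nM = 1e-9 mol/L; molecules per nM = NA * V[L] * 1e-9
  count / (.AVOGADRO * compartment$volume_pl * 1e-12 * 1e-9)
}

#' @rdname convert_units
#' @param conc_nM concentration in nM.
#' @export
convert_units_inverse <- function(conc_nM, compartment) {
  if (is.null(compartment$volume_pl)) stop("unknown compartment", call. = FALSE)
  conc_nM * (.AVOGADRO * compartment$volume_pl * 1e-12 * 1e-9)
}

# internal: construct one reaction.
# rate: character, an R expression in state/parameter/input symbols, >= 0
# for non-negative concentrations.
# effects: named numeric, d(concentration)/dt contribution per unit rate;
# cross-compartment transport carries the volume ratio so that amounts are
# conserved.
.reaction <- function(name, rate, effects) {
  list(name = name, rate = rate, effects = effects)
}

#' Gene module definition
#'
#' Per-gene transcription/degradation parameters for one acute-phase gene.
#' Delayed genes (`tau` non-NULL) route transcription through a nuclear
#' 5-step linear chain with per-step rate 5/tau, giving an Erlang(5)
#' transit-time distribution with mean tau.
#'
#' @param gene one of [app_genes()].
#' @param k_txn transcription rate per unit active STAT3 (nM/h per nM).
#' @param k_txn_basal basal transcription rate (nM/h), multiplied by the
#'   gene's control drift when one is attached.
#' @param k_mrna_deg first-order cytoplasmic mRNA degradation rate (1/h).
#' @param tau transcriptional delay in hours, or NULL for Apcs/Hamp.
#' @param txn_hill optional Hill exponent on the STAT3 dependence of
#'   transcription (default 1, the plain linear law). Values > 1 lower the
#'   apparent IL-6 sensitivity of the gene.
#' @return object of class `hep_gene_module`.
#' @export
gene_module <- function(gene, k_txn, k_txn_basal, k_mrna_deg,
                        tau = NULL, txn_hill = 1) {
  if (!gene %in% app_genes()) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  if (!is.null(tau) && gene %in% c("Apcs", "Hamp")) {
    stop("gene ", gene, " carries no delay chain; tau must be NULL",
         call. = FALSE)
  }
  stopifnot(k_txn >= 0, k_txn_basal >= 0, k_mrna_deg > 0,
            is.null(tau) || tau > 0, txn_hill > 0)
  structure(
    list(gene = gene, k_txn = k_txn, k_txn_basal = k_txn_basal,
         k_mrna_deg = k_mrna_deg, tau = tau, txn_hill = txn_hill),
    class = "hep_gene_module"
  )
}

#' Assemble the core IL-6/JAK1-STAT3/SOCS3 reaction network
#'
#' Builds the two-compartment mass-action network: receptor complex
#' synthesis, SOCS3-enhanced degradation of all receptor states, IL-6
#' dependent JAK1 activation and gp130 phosphorylation (both inhibited by
#' Ruxolitinib), coupled receptor dephosphorylation, STAT3 activation by the
#' fully active receptor (inhibited by SOCS3 and Stattic),
#' nucleocytoplasmic STAT3 shuttling (no export of phosphorylated STAT3;
#' nuclear dephosphorylation is fast and folded into the import step),
#' delayed Socs3 transcription through a 5-step nuclear chain, SOCS3
#' translation/turnover, and first-order Ruxolitinib decay.
#'
#' Transcription is driven directly by cytoplasmic pSTAT3; the
#' proportionality constant between cytoplasmic and nuclear active STAT3 is
#' absorbed into the transcription rate constants.
#'
#' @param core_params named numeric vector/list with all 22
#'   [core_parameter_names()], strictly positive.
#' @param compartments from [hep_compartments()].
#' @param fixed_totals named numeric: absolute molecule counts per cell;
#'   must contain `STAT3` (total STAT3, sets the conserved amount).
#' @return object of class `hep_network`.
#' @export
build_core_model <- function(core_params,
                             compartments = hep_compartments(),
                             fixed_totals = c(STAT3 = 2e6)) {
  core_params <- unlist(core_params)
  missing <- setdiff(core_parameter_names(), names(core_params))
  if (length(missing)) {
    stop("missing core parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  core_params <- core_params[core_parameter_names()]
  if (any(!is.finite(core_params)) || any(core_params <= 0)) {
    bad <- names(core_params)[!is.finite(core_params) | core_params <= 0]
    stop("non-positive core parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.na(fixed_totals["STAT3"]) || fixed_totals[["STAT3"]] <= 0) {
    stop("fixed_totals must contain a positive STAT3 molecule count",
         call. = FALSE)
  }
  Vc <- compartments$cytoplasm$volume_pl
  Vn <- compartments$nucleus$volume_pl
  c2n <- Vc / Vn   # concentration gain cytoplasm -> nucleus transport
  n2c <- Vn / Vc

  species <- data.frame(
    name = c("JAK1_gp130", "pJAK1_gp130", "pJAK1_pgp130",
             "STAT3", "pSTAT3", "SOCS3", "Socs3RNA", "Rux",
             "nSTAT3", paste0("nSocs3RNA", 1:5)),
    compartment = c(rep("cytoplasm", 8), rep("nucleus", 6)),
    stringsAsFactors = FALSE
  )

  frux <- "/(1 + Rux/Ki_rux)"
  recdeg <- "(k_rec_deg + k_socs3_recdeg*SOCS3)"
  reactions <- list(
    .reaction("rec_syn", "k_rec_syn", c(JAK1_gp130 = 1)),
    .reaction("rec_deg", paste0(recdeg, "*JAK1_gp130"), c(JAK1_gp130 = -1)),
    .reaction("rec_deg_p1", paste0(recdeg, "*pJAK1_gp130"),
              c(pJAK1_gp130 = -1)),
    .reaction("rec_deg_p2", paste0(recdeg, "*pJAK1_pgp130"),
              c(pJAK1_pgp130 = -1)),
    .reaction("jak_act",
              paste0("(k_jak_act_basal + k_jak_act_il6*IL6)*JAK1_gp130", frux),
              c(JAK1_gp130 = -1, pJAK1_gp130 = 1)),
    .reaction("gp130_phos", paste0("k_gp130_phos*pJAK1_gp130", frux),
              c(pJAK1_gp130 = -1, pJAK1_pgp130 = 1)),
    .reaction("deact1", "k_deact1*pJAK1_gp130",
              c(pJAK1_gp130 = -1, JAK1_gp130 = 1)),
    .reaction("deact2", "k_deact2*pJAK1_pgp130",
              c(pJAK1_pgp130 = -1, JAK1_gp130 = 1)),
    .reaction("stat3_act",
              paste0("k_stat3_act*pJAK1_pgp130*STAT3",
                     "/(1 + SOCS3/Ki_socs3)/(1 + Stattic/Ki_stattic)"),
              c(STAT3 = -1, pSTAT3 = 1)),
    .reaction("stat3_imp", "k_stat3_imp*STAT3",
              c(STAT3 = -1, nSTAT3 = c2n)),
    .reaction("pstat3_imp", "k_pstat3_imp*pSTAT3",
              c(pSTAT3 = -1, nSTAT3 = c2n)),
    .reaction("stat3_exp", "k_stat3_exp*nSTAT3",
              c(nSTAT3 = -1, STAT3 = n2c)),
    .reaction("socs3_txn",
              "(k_socs3_txn_basal + k_socs3_txn*pSTAT3)*actd_gate",
              c(nSocs3RNA1 = 1)),
    .reaction("socs3_chain1", "(5/tau_socs3)*nSocs3RNA1",
              c(nSocs3RNA1 = -1, nSocs3RNA2 = 1)),
    .reaction("socs3_chain2", "(5/tau_socs3)*nSocs3RNA2",
              c(nSocs3RNA2 = -1, nSocs3RNA3 = 1)),
    .reaction("socs3_chain3", "(5/tau_socs3)*nSocs3RNA3",
              c(nSocs3RNA3 = -1, nSocs3RNA4 = 1)),
    .reaction("socs3_chain4", "(5/tau_socs3)*nSocs3RNA4",
              c(nSocs3RNA4 = -1, nSocs3RNA5 = 1)),
    .reaction("socs3_export", "(5/tau_socs3)*nSocs3RNA5",
              c(nSocs3RNA5 = -1, Socs3RNA = n2c)),
    .reaction("socs3_mrna_deg", "k_socs3_mrna_deg*Socs3RNA",
              c(Socs3RNA = -1)),
    .reaction("socs3_trl", "k_socs3_trl*Socs3RNA", c(SOCS3 = 1)),
    .reaction("socs3_deg", "k_socs3_deg*SOCS3", c(SOCS3 = -1)),
    .reaction("rux_decay", "k_rux_deg*Rux", c(Rux = -1))
  )

  stat3_total_nM <- convert_units(fixed_totals[["STAT3"]],
                                  compartments$cytoplasm)
  init <- stats::setNames(numeric(nrow(species)), species$name)
  init["STAT3"] <- stat3_total_nM

  net <- structure(
    list(species = species,
         reactions = reactions,
         inputs = c("IL6", "Stattic", "ActD"),
         parameters = core_parameter_names(),
         compartments = compartments,
         fixed_totals = fixed_totals,
         init = init,
         genes = list(),
         drift = list(),
         compiled = NULL),
    class = "hep_network"
  )
  net
}

#' Append one acute-phase gene module to a network
#'
#' Adds transcription (basal rate, optionally multiplied by a control drift,
#' plus a pSTAT3-driven term, both gated off by actinomycin D), a 5-step
#' nuclear delay chain when the gene carries a delay, nuclear export, and
#' first-order cytoplasmic mRNA degradation. A cumulative-integral state
#' `IntRNA_<gene>` is appended alongside so that integrated responses are
#' available directly from the solver. Gene modules never feed back into the
#' core network.
#'
#' @param network a `hep_network` from [build_core_model()].
#' @param gene a [gene_module()].
#' @return the extended network.
#' @export
build_gene_extension <- function(network, gene) {
  stopifnot(inherits(network, "hep_network"),
            inherits(gene, "hep_gene_module"))
  g <- gene$gene
  if (g %in% names(network$genes)) {
    stop("gene ", g, " already present in network", call. = FALSE)
  }
  Vc <- network$compartments$cytoplasm$volume_pl
  Vn <- network$compartments$nucleus$volume_pl
  n2c <- Vn / Vc

  p_txn <- paste0("k_txn_", g)
  p_bas <- paste0("k_txn_basal_", g)
  p_deg <- paste0("k_mrna_deg_", g)
  p_tau <- paste0("tau_", g)
  mrna <- paste0("AppRNA_", g)
  intg <- paste0("IntRNA_", g)

  stat3_term <- if (gene$txn_hill == 1) "pSTAT3" else
    sprintf("pSTAT3^%s", format(gene$txn_hill))
  txn_rate <- sprintf("(%s*drift_%s_t + %s*%s)*actd_gate",
                      p_bas, g, p_txn, stat3_term)

  new_params <- c(p_txn, p_bas, p_deg)
  reactions <- list()
  if (!is.null(gene$tau)) {
    chain <- paste0("nAppRNA_", g, "_", 1:5)
    new_species <- data.frame(
      name = c(chain, mrna, intg),
      compartment = c(rep("nucleus", 5), "cytoplasm", "cytoplasm"),
      stringsAsFactors = FALSE
    )
    step <- sprintf("(5/%s)", p_tau)
    reactions <- c(reactions, list(
      .reaction(paste0("txn_", g), txn_rate,
                stats::setNames(1, chain[1]))))
    for (i in 1:4) {
      reactions <- c(reactions, list(
        .reaction(paste0("chain_", g, "_", i),
                  paste0(step, "*", chain[i]),
                  stats::setNames(c(-1, 1), chain[i:(i + 1)]))))
    }
    reactions <- c(reactions, list(
      .reaction(paste0("export_", g), paste0(step, "*", chain[5]),
                stats::setNames(c(-1, n2c), c(chain[5], mrna)))))
    new_params <- c(new_params, p_tau)
  } else {
    new_species <- data.frame(
      name = c(mrna, intg),
      compartment = c("cytoplasm", "cytoplasm"),
      stringsAsFactors = FALSE
    )
    reactions <- c(reactions, list(
      .reaction(paste0("txn_", g), txn_rate, stats::setNames(1, mrna))))
  }
  reactions <- c(reactions, list(
    .reaction(paste0("mrna_deg_", g), paste0(p_deg, "*", mrna),
              stats::setNames(-1, mrna)),
    .reaction(paste0("integ_", g), mrna, stats::setNames(1, intg))
  ))

  network$species <- rbind(network$species, new_species)
  network$reactions <- c(network$reactions, reactions)
  network$parameters <- c(network$parameters, new_params)
  network$init <- c(network$init,
                    stats::setNames(numeric(nrow(new_species)),
                                    new_species$name))
  network$genes[[g]] <- gene
  network$compiled <- NULL
  network
}

#' Gene parameter names for a gene module
#' @param gene a `hep_gene_module` or gene name plus `delayed` flag.
#' @keywords internal
gene_parameter_names <- function(gene) {
  g <- if (inherits(gene, "hep_gene_module")) gene$gene else gene
  delayed <- if (inherits(gene, "hep_gene_module")) !is.null(gene$tau)
             else g %in% delayed_genes()
  nm <- paste0(c("k_txn_", "k_txn_basal_", "k_mrna_deg_"), g)
  if (delayed) nm <- c(nm, paste0("tau_", g))
  nm
}

#' Count the free dynamic parameters of a network
#' @param network a `hep_network`.
#' @return integer.
#' @export
n_dynamic_parameters <- function(network) length(network$parameters)

#' Evaluate every reaction rate law at a given state
#'
#' Returns the named vector of reaction rates; used for reaction-level
#' verification of the generated right-hand side.
#'
#' @param network a `hep_network`.
#' @param state named state vector (nM).
#' @param params named parameter vector.
#' @param inputs named vector with IL6, Stattic, ActD.
#' @return named numeric vector of rates.
#' @export
reaction_rates <- function(network, state, params,
                           inputs = c(IL6 = 0, Stattic = 0, ActD = 0)) {
  env <- new.env(parent = baseenv())
  for (nm in names(state)) assign(nm, state[[nm]], envir = env)
  for (nm in names(params)) assign(nm, params[[nm]], envir = env)
  for (nm in network$inputs) assign(nm, unname(inputs[nm]), envir = env)
  assign("actd_gate", if (inputs[["ActD"]] > 0) 0 else 1, envir = env)
  assign("t", 0, envir = env)
  for (g in names(network$genes)) {
    fn <- network$drift[[g]]
    val <- if (is.null(fn)) 1 else fn(0)
    assign(paste0("drift_", g, "_t"), val, envir = env)
  }
  v <- vapply(network$reactions,
              function(r) eval(parse(text = r$rate), envir = env),
              numeric(1), USE.NAMES = FALSE)
  stats::setNames(v, vapply(network$reactions, `[[`, "", "name"))
}

#' Attach a control-drift function to a gene
#'
#' The drift multiplies the gene's basal transcription rate as a function of
#' time; used to represent slow expression changes in untreated control
#' cells.
#'
#' @param network a `hep_network`.
#' @param gene gene name.
#' @param fn function of time (hours) returning a positive multiplier.
#' @return the network.
#' @export
set_gene_drift <- function(network, gene, fn) {
  if (!gene %in% names(network$genes)) {
    stop("gene ", gene, " not in network", call. = FALSE)
  }
  stopifnot(is.function(fn))
  network$drift[[gene]] <- fn
  network$compiled <- NULL
  network
}

# -- code generation ---------------------------------------------------------

#' Compile a network for integration
#'
#' Compiles the declarative reaction list into an ODE right-hand side and an
#' analytic Jacobian. Both are generated as straight-line R code (one local
#' variable per state/parameter/rate) so that a single call costs tens of
#' microseconds; the Jacobian is derived symbolically with [stats::D()] on
#' each rate law. Called automatically by the simulation entry points; the
#' compiled functions are exposed for testing against oracles.
#'
#' @param network a `hep_network`.
#' @return the network with a `compiled` element holding `rhs(t, y, p)` and
#'   `jac(t, y, p)`.
#' @export
compile_network <- function(network) {
  if (!is.null(network$compiled)) return(network)
  st <- network$species$name
  n <- length(st)
  pn <- network$parameters
  inp <- network$inputs

  lines <- character(0)
  lines <- c(lines, sprintf("  %s <- y[%dL]", st, seq_len(n)))
  lines <- c(lines, sprintf("  %s <- parms[[\"%s\"]]", c(pn, inp), c(pn, inp)))
  lines <- c(lines, "  actd_gate <- if (ActD > 0) 0 else 1")
  for (g in names(network$genes)) {
    fn <- network$drift[[g]]
    if (is.null(fn)) {
      lines <- c(lines, sprintf("  drift_%s_t <- 1", g))
    } else {
      lines <- c(lines, sprintf("  drift_%s_t <- .drift[[\"%s\"]](t)", g, g))
    }
  }
  nr <- length(network$reactions)
  rate_sym <- sprintf("v%03d", seq_len(nr))
  lines <- c(lines, sprintf("  %s <- %s", rate_sym,
                            vapply(network$reactions, `[[`, "", "rate")))

  # assemble dy
  terms <- vector("list", n)
  names(terms) <- st
  for (j in seq_len(nr)) {
    eff <- network$reactions[[j]]$effects
    for (s in names(eff)) {
      if (!s %in% st) stop("unknown species in reaction effects: ", s,
                           call. = FALSE)
      coef <- eff[[s]]
      term <- if (coef == 1) paste0("+", rate_sym[j])
              else if (coef == -1) paste0("-", rate_sym[j])
              else sprintf("%+.17g*%s", coef, rate_sym[j])
      terms[[s]] <- c(terms[[s]], term)
    }
  }
  lines <- c(lines, sprintf("  dy <- numeric(%dL)", n))
  for (i in seq_len(n)) {
    rhs <- if (length(terms[[i]])) paste(terms[[i]], collapse = " ") else "0"
    lines <- c(lines, sprintf("  dy[%dL] <- %s", i, rhs))
  }
  rhs_text <- paste(c("function(t, y, parms) {", lines, "  list(dy)", "}"),
                    collapse = "\n")

  # Jacobian: J[i, j] = sum_r effects[r, i] * d rate_r / d y_j
  jac_entries <- vector("list", 0)
  for (j in seq_len(nr)) {
    rexpr <- parse(text = network$reactions[[j]]$rate)[[1]]
    vars <- intersect(all.vars(rexpr), st)
    eff <- network$reactions[[j]]$effects
    for (v in vars) {
      dv <- stats::D(rexpr, v)
      dtxt <- paste(deparse(dv), collapse = " ")
      col <- match(v, st)
      for (s in names(eff)) {
        row <- match(s, st)
        coef <- eff[[s]]
        term <- if (coef == 1) sprintf("+(%s)", dtxt)
                else if (coef == -1) sprintf("-(%s)", dtxt)
                else sprintf("%+.17g*(%s)", coef, dtxt)
        key <- sprintf("%d_%d", row, col)
        jac_entries[[key]] <- c(jac_entries[[key]], term)
      }
    }
  }
  jlines <- character(0)
  jlines <- c(jlines, sprintf("  %s <- y[%dL]", st, seq_len(n)))
  jlines <- c(jlines, sprintf("  %s <- parms[[\"%s\"]]",
                              c(pn, inp), c(pn, inp)))
  jlines <- c(jlines, "  actd_gate <- if (ActD > 0) 0 else 1")
  for (g in names(network$genes)) {
    fn <- network$drift[[g]]
    if (is.null(fn)) {
      jlines <- c(jlines, sprintf("  drift_%s_t <- 1", g))
    } else {
      jlines <- c(jlines, sprintf("  drift_%s_t <- .drift[[\"%s\"]](t)", g, g))
    }
  }
  jlines <- c(jlines, sprintf("  J <- matrix(0, %dL, %dL)", n, n))
  for (key in names(jac_entries)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    jlines <- c(jlines, sprintf("  J[%dL, %dL] <- %s", ij[1], ij[2],
                                paste(jac_entries[[key]], collapse = " ")))
  }
  jac_text <- paste(c("function(t, y, parms) {", jlines, "  J", "}"),
                    collapse = "\n")

  env <- new.env(parent = baseenv())
  env$.drift <- network$drift
  rhs <- eval(parse(text = rhs_text), envir = env)
  jac <- eval(parse(text = jac_text), envir = env)

  network$compiled <- list(rhs = rhs, jac = jac,
                           state_names = st,
                           rhs_text = rhs_text, jac_text = jac_text)
  network
}
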