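test_that("core model exposes the canonical 22-parameter table", {
  expect_length(core_parameter_names(), 22L)
  expect_false(anyDuplicated(core_parameter_names()) > 0)
  expect_identical(n_dynamic_parameters(CORE_NET), 22L)
  expect_setequal(CORE_NET$parameters, core_parameter_names())
})

test_that("full network adds 26 gene parameters (7x3 + 5 delays)", {
  expect_identical(n_dynamic_parameters(NET), 48L)
  expect_setequal(names(PVEC), NET$parameters)
})

test_that("unit conversion round-trips and scales with volume", {
  comp <- hep_compartments()
  x <- c(0, 1, 2e6, 7.3e4)
  expect_equal(convert_units_inverse(convert_units(x, comp$cytoplasm),
                                     comp$cytoplasm), x,
               tolerance = 1e-12)
  # same count is a higher concentration in the smaller nucleus
  expect_gt(convert_units(1e5, comp$nucleus),
            convert_units(1e5, comp$cytoplasm))
  expect_error(convert_units(-1, comp$cytoplasm), "count")
  expect_error(hep_compartments(cytoplasm_pl = -1), "positive")
})

test_that("generated RHS equals the reaction-by-reaction oracle", {
  net <- compile_network(NET)
  set.seed(42)
  y <- stats::setNames(stats::runif(length(net$init), 0.01, 5),
                       names(net$init))
  inputs <- c(IL6 = 12, Stattic = 0, ActD = 0)
  params <- PVEC
  rates <- reaction_rates(net, y, params, inputs)
  expect_true(all(rates >= 0))
  dy_oracle <- stats::setNames(numeric(length(y)), names(y))
  for (r in net$reactions) {
    for (s in names(r$effects)) {
      dy_oracle[s] <- dy_oracle[s] + r$effects[[s]] * rates[[r$name]]
    }
  }
  parms <- c(as.list(params), as.list(inputs))
  dy <- net$compiled$rhs(0, y, parms)[[1]]
  expect_equal(unname(dy), unname(dy_oracle), tolerance = 1e-12)
})

test_that("analytic Jacobian matches central finite differences", {
  net <- compile_network(NET)
  set.seed(7)
  y <- stats::setNames(stats::runif(length(net$init), 0.05, 3),
                       names(net$init))
  parms <- c(as.list(PVEC), list(IL6 = 40, Stattic = 100, ActD = 0))
  J <- net$compiled$jac(0.5, y, parms)
  h <- 1e-6
  for (j in sample(seq_along(y), 12)) {
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    fd <- (net$compiled$rhs(0.5, yp, parms)[[1]] -
             net$compiled$rhs(0.5, ym, parms)[[1]]) / (2 * h)
    expect_equal(J[, j], fd, tolerance = 1e-5)
  }
})

test_that("ActD gates every transcription flux to exactly zero", {
  net <- NET
  y <- net$init
  y["pSTAT3"] <- 2; y["STAT3"] <- 10
  rates <- reaction_rates(net, y, PVEC, c(IL6 = 40, Stattic = 0, ActD = 1))
  txn <- grep("^(socs3_txn|txn_)", names(rates), value = TRUE)
  expect_length(txn, 8L)  # Socs3 + 7 genes
  expect_identical(unname(rates[txn]), rep(0, 8L))
  rates_on <- reaction_rates(net, y, PVEC, c(IL6 = 40, Stattic = 0, ActD = 0))
  expect_true(all(rates_on[txn] > 0))
})

test_that("gene module validation", {
  expect_error(gene_module("Apcs", 1, 1, 1, tau = 2), "no delay chain")
  expect_error(gene_module("Hamp", 1, 1, 1, tau = 2), "no delay chain")
  expect_error(gene_module("Notagene", 1, 1, 1), "unknown gene")
  expect_error(build_gene_extension(CORE_NET, REF$genes$Fgg),
               NA)
  net2 <- build_gene_extension(CORE_NET, REF$genes$Fgg)
  expect_error(build_gene_extension(net2, REF$genes$Fgg),
               "already present")
})

test_that("cross-compartment stoichiometry carries the volume ratio", {
  exp_r <- NET$reactions[[which(vapply(NET$reactions, `[[`, "", "name") ==
                                  "stat3_imp")]]
  Vc <- REF$compartments$cytoplasm$volume_pl
  Vn <- REF$compartments$nucleus$volume_pl
  expect_equal(unname(exp_r$effects["nSTAT3"]), Vc / Vn)
  expect_equal(unname(exp_r$effects["STAT3"]), -1)
})

test_that("missing or non-positive core parameters are rejected", {
  p <- REF$core
  expect_error(build_core_model(p[-1]), "missing core parameter")
  p2 <- p; p2["k_rec_syn"] <- 0
  expect_error(build_core_model(p2), "non-positive")
})
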