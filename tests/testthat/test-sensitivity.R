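test_that("integral-state and trapezoid integration agree", {
  a <- integrated_response(NET, PVEC, "Fgg", il6 = 100, horizon = 24,
                           method = "ode")
  b <- integrated_response(NET, PVEC, "Fgg", il6 = 100, horizon = 24,
                           method = "trapezoid", dt = 0.01)
  expect_gt(a, 0)
  expect_lt(abs(a - b) / a, 1e-6)
})

test_that("lpsa equals the finite-difference oracle", {
  pars <- c("k_stat3_act", "k_mrna_deg_Fgg")
  s <- lpsa(NET, PVEC, parameters = pars, perturbation = 0.5,
            il6 = 100, horizon = 24)
  genes <- names(NET$genes)
  y_ref <- vapply(genes, function(g)
    integrated_response(NET, PVEC, g, il6 = 100, horizon = 24), numeric(1))
  for (pn in pars) {
    p2 <- PVEC
    p2[pn] <- PVEC[[pn]] * 1.5
    y <- vapply(genes, function(g)
      integrated_response(NET, p2, g, il6 = 100, horizon = 24), numeric(1))
    oracle <- ((y - y_ref) / y_ref) / 0.5
    got <- as.numeric(s[s$parameter == pn, paste0("S_", genes)])
    expect_equal(got, unname(oracle), tolerance = 1e-8)
    expect_equal(s$S_mean[s$parameter == pn], mean(oracle),
                 tolerance = 1e-8)
  }
})

test_that("signature sensitivities have the expected signs", {
  s <- lpsa(NET, PVEC,
            parameters = c("k_stat3_act", "Ki_socs3", "k_rec_deg"))
  sm <- stats::setNames(s$S_mean, s$parameter)
  expect_gt(sm[["k_stat3_act"]], 0)   # more activation, more output
  expect_gt(sm[["Ki_socs3"]], 0)      # weaker feedback, more output
  expect_lt(sm[["k_rec_deg"]], 0)     # faster receptor loss, less output
})

test_that("gene degradation rate only affects its own gene", {
  s <- lpsa(NET, PVEC, parameters = "k_mrna_deg_Hamp")
  expect_lt(s[["S_Hamp"]], 0)
  others <- paste0("S_", setdiff(names(NET$genes), "Hamp"))
  expect_true(all(abs(as.numeric(s[, others])) < 1e-6))
})

test_that("uncertainty envelopes bracket the point estimate", {
  fake_profile <- structure(
    list(param = "Ki_socs3",
         profile = data.frame(
           value = REF$core[["Ki_socs3"]] * c(0.7, 1.4),
           objective = c(1, 2), converged = TRUE),
         best_objective = 1, threshold = 3.84,
         lower = NA, upper = NA),
    class = "hep_profile")
  env <- lpsa_uncertainty(NET, PVEC, profiles = list(fake_profile),
                          parameters = "k_stat3_act")
  expect_lte(env$S_min, env$S_mean)
  expect_gte(env$S_max, env$S_mean)
  expect_gt(env$S_max - env$S_min, 0)
  expect_error(lpsa_uncertainty(NET, PVEC, profiles = list()), "empty")
})

test_that("invalid sensitivity inputs are rejected", {
  expect_error(integrated_response(NET, PVEC, "Fgg", horizon = -1), "> 0")
})
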