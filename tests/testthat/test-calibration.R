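test_that("control drift is monotone, normalized and clamped", {
  d <- fit_control_drift(c(0, 6, 24, 48), c(1, 0.82, 0.55, 0.4))
  expect_equal(d$direction, "decreasing")
  expect_equal(d$fun(0), 1)
  tt <- seq(0, 48, by = 0.5)
  expect_true(all(diff(d$fun(tt)) <= 1e-12))
  expect_equal(d$fun(-5), d$fun(0))      # clamped below the first knot
  expect_equal(d$fun(100), d$fun(48))    # clamped above the last knot
  # replicates at the same time are averaged; non-monotone data isotonized
  d2 <- fit_control_drift(c(0, 0, 6, 24), c(1, 1.2, 1.5, 2))
  expect_equal(d2$direction, "increasing")
  expect_true(all(diff(d2$fun(seq(0, 24, 0.5))) >= -1e-12))
  dc <- fit_control_drift(c(0, 10), c(2, 2))
  expect_equal(dc$fun(c(0, 5, 10)), c(1, 1, 1))
  expect_error(fit_control_drift(c(0, NA), c(1, 1)), "non-finite")
})

# small fast-path problem shared by the calibration tests
gene_fixture <- local({
  times <- c(0.5, 1, 2, 4, 8, 16, 24)
  protocols <- list(tc = stimulation_protocol(40, times, label = "tc"))
  obs <- default_observables()["Apcs_mrna"]
  sim <- gene_simulator(NET, PVEC, "Apcs", protocols)
  pred <- as.numeric(sim(PVEC, "tc", times)$states[, 1])
  list(times = times, protocols = protocols, obs = obs, sim = sim,
       pred = pred)
})

test_that("objective is invariant to the gel-scale gauge", {
  fx <- gene_fixture
  mk_data <- function(v) data.frame(
    experiment = "tc", observable = "Apcs_mrna", time_h = fx$times,
    replicate = 1, value = v, gel_id = "g1")
  prob1 <- fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                       protocols = fx$protocols, observables = fx$obs,
                       data = mk_data(fx$pred),
                       sigma = c(qpcr_time = 0.1), simulator = fx$sim)
  prob2 <- fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                       protocols = fx$protocols, observables = fx$obs,
                       data = mk_data(3.7 * fx$pred),
                       sigma = c(qpcr_time = 0.1), simulator = fx$sim)
  o1 <- objective_value(prob1, details = TRUE)
  o2 <- objective_value(prob2, details = TRUE)
  expect_equal(o1$objective, o2$objective, tolerance = 1e-9)
  expect_equal(o2$scales[[1]] / o1$scales[[1]], 3.7, tolerance = 1e-9)
  expect_lt(max(abs(o2$residuals)), 1e-9)
})

test_that("objective at the truth concentrates as chi-square", {
  fx <- gene_fixture
  set.seed(20)
  n_rep <- 4
  sigma <- 0.1
  d <- data.frame(
    experiment = "tc", observable = "Apcs_mrna",
    time_h = rep(fx$times, n_rep),
    replicate = rep(seq_len(n_rep), each = length(fx$times)),
    value = rep(fx$pred, n_rep) +
      stats::rnorm(length(fx$times) * n_rep, 0, sigma),
    gel_id = "g1")
  prob <- fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                      protocols = fx$protocols, observables = fx$obs,
                      data = d, sigma = c(qpcr_time = sigma),
                      simulator = fx$sim)
  o <- objective_value(prob)
  N <- nrow(d)
  expected <- N * (1 + log(2 * pi * sigma^2))
  expect_lt(abs(o - expected), 3 * sqrt(2 * N))
})

test_that("multi-start fit recovers the degradation rate; profile covers truth", {
  fx <- gene_fixture
  truth <- PVEC
  truth["k_mrna_deg_Apcs"] <- 0.2
  pred_t <- as.numeric(fx$sim(truth, "tc", fx$times)$states[, 1])
  set.seed(30)
  d <- data.frame(
    experiment = "tc", observable = "Apcs_mrna",
    time_h = rep(fx$times, 2), replicate = rep(1:2, each = length(fx$times)),
    value = rep(pred_t, 2) + stats::rnorm(2 * length(fx$times), 0, 0.02),
    gel_id = "g1")
  prob <- fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                      protocols = fx$protocols, observables = fx$obs,
                      data = d, sigma = c(qpcr_time = 0.02),
                      lower = 1e-3, upper = 1e2, simulator = fx$sim)
  fit <- fit_params(prob, n_starts = 5, seed = 4)
  expect_lt(abs(fit$par[["k_mrna_deg_Apcs"]] - 0.2) / 0.2, 0.2)
  # waterfall is sorted and reproducible
  expect_true(!is.unsorted(fit$waterfall$objective))
  fit2 <- fit_params(prob, n_starts = 5, seed = 4)
  expect_identical(fit$par, fit2$par)

  prof <- profile_likelihood(prob, fit, "k_mrna_deg_Apcs",
                             span = 1, n_grid = 9)
  expect_gte(0.2, prof$lower)
  expect_lte(0.2, prof$upper)
  # profile objective is never below the refitted optimum
  expect_true(all(prof$profile$objective >= prof$best_objective - 1e-6))
  expect_lte(min(prof$profile$objective), prof$best_objective + 1e-6)
})

test_that("fit_genes fits each gene independently on its own data", {
  fx <- gene_fixture
  truth <- PVEC
  truth["k_mrna_deg_Apcs"] <- 0.25
  pred_t <- as.numeric(fx$sim(truth, "tc", fx$times)$states[, 1])
  d <- data.frame(
    experiment = "tc", observable = "Apcs_mrna", time_h = fx$times,
    replicate = 1, value = pred_t, gel_id = "g1")
  fits <- fit_genes(NET, PVEC, PVEC, fx$protocols,
                    default_observables(), d,
                    n_starts = 3, seed = 2, sigma = c(qpcr_time = 0.05),
                    lower = 1e-3, upper = 1e2)
  expect_identical(names(fits), "Apcs")
  expect_lt(abs(fits$Apcs$par[["k_mrna_deg_Apcs"]] - 0.25) / 0.25, 0.1)
})

test_that("fast gene simulator matches the full network", {
  times <- c(0.5, 1, 3, 6, 12, 24)
  protocols <- list(tc = stimulation_protocol(40, times, label = "tc"))
  sim <- gene_simulator(NET, PVEC, "Fgg", protocols)
  fast <- as.numeric(sim(PVEC, "tc", times)$states[, 1])
  tr <- simulate_protocol(NET, PVEC, protocols$tc)
  full <- trajectory_states(tr, times)[, "AppRNA_Fgg"]
  expect_equal(fast, unname(full), tolerance = 1e-4)
})

test_that("problem assembly validates its inputs", {
  fx <- gene_fixture
  d <- data.frame(experiment = "nope", observable = "Apcs_mrna",
                  time_h = 1, replicate = 1, value = 1)
  expect_error(
    fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                protocols = fx$protocols, observables = fx$obs, data = d,
                simulator = fx$sim),
    "unknown experiment")
  d$experiment <- "tc"; d$observable <- "nope"
  expect_error(
    fit_problem(base_params = PVEC, free = "k_mrna_deg_Apcs",
                protocols = fx$protocols, observables = fx$obs, data = d,
                simulator = fx$sim),
    "unknown observable")
})
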