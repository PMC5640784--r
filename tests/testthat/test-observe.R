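make_traj <- function(states_list, times = seq_along(states_list[[1]]) - 1) {
  states <- do.call(cbind, states_list)
  structure(list(times = times, states = states,
                 compartments = hep_compartments()),
            class = "hep_trajectory")
}

test_that("phospho-degree is the amount fraction across compartments", {
  tr <- make_traj(list(STAT3 = c(10, 8), pSTAT3 = c(0, 4),
                       nSTAT3 = c(10, 20)))
  Vc <- 12.67; Vn <- 0.5
  expect_equal(phospho_degree(tr, 0), 0)
  expect_equal(phospho_degree(tr, 1),
               4 * Vc / ((8 + 4) * Vc + 20 * Vn))
})

test_that("nuc/cyt ratio uses per-compartment concentrations", {
  tr <- make_traj(list(STAT3 = c(10, 5), pSTAT3 = c(0, 5),
                       nSTAT3 = c(10, 30)))
  expect_equal(nuc_cyt_ratio(tr, c(0, 1)), c(1, 3))
})

test_that("predict_observable applies formula, scale, offset, transform", {
  tr <- make_traj(list(A = c(1, 2), B = c(3, 4)))
  ob <- observable("x", c(A = 1, B = 2))
  expect_equal(predict_observable(tr, ob, scale = 10, offset = 1),
               10 * c(7, 10) + 1)
  ob_log <- observable("x", c(A = 1), transform = "log10")
  expect_equal(predict_observable(tr, ob_log, scale = 100),
               log10(100 * c(1, 2)))
})

test_that("absolute observables ignore nuisance parameters", {
  tr <- make_traj(list(STAT3 = c(10), pSTAT3 = c(10), nSTAT3 = c(5),
                       A = c(1)))
  ob <- observable("pd", "phospho_degree")
  expect_true(ob$absolute)
  expect_equal(predict_observable(tr, ob, scale = 100, offset = 5),
               predict_observable(tr, ob))
})

test_that("log10 of a non-positive prediction names the offender", {
  tr <- make_traj(list(A = c(1, 0)))
  ob <- observable("gene_x", c(A = 1), transform = "log10")
  expect_error(predict_observable(tr, ob), "gene_x at t = 1")
})

test_that("unknown species in a formula is reported", {
  tr <- make_traj(list(A = c(1)))
  ob <- observable("x", c(Missing = 1))
  expect_error(predict_observable(tr, ob), "unknown species: Missing")
})

test_that("default observable set covers the calibration classes", {
  obs <- default_observables()
  classes <- vapply(obs, `[[`, "", "class")
  expect_true(all(c("immunoblot", "qpcr_time", "qpcr_dose", "massspec",
                    "imaging") %in% classes))
  expect_true(all(paste0(app_genes(), "_mrna") %in% names(obs)))
  # dose-response observables are read on the log scale
  expect_identical(obs$Socs3_mrna_dose$transform, "log10")
})
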