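test_that("the calibration suite is deterministic per seed", {
  s1 <- generate_suite(REF, seed = 5, network = NET)
  s2 <- generate_suite(REF, seed = 5, network = NET)
  expect_identical(s1, s2)
  s3 <- generate_suite(REF, seed = 6, network = NET)
  expect_false(identical(s1$value, s3$value))
  expect_true(all(c("experiment", "observable", "time_h", "replicate",
                    "value", "gel_id") %in% names(s1)))
  expect_false(anyNA(s1$value))
})

test_that("the suite covers every required experiment class", {
  s <- generate_suite(REF, seed = 5, network = NET)
  expect_true(all(c("pJAK1", "pgp130", "pSTAT3", "tSTAT3", "SOCS3") %in%
                    s$observable))                          # immunoblot
  expect_true(all(paste0(app_genes(), "_mrna") %in% s$observable))
  expect_true(all(paste0(app_genes(), "_mrna_dose") %in% s$observable))
  expect_true(any(grepl("^dose_", s$experiment)))           # dose responses
  expect_true(all(c("rux_pre", "stattic_pre", "pulse30") %in% s$experiment))
  expect_true("phospho_degree" %in% s$observable)           # mass spec
  expect_true("nuc_cyt_ratio" %in% s$observable)            # imaging
  # Stattic exposure is capped at 2 h of experiment time
  expect_lte(max(s$time_h[s$experiment == "stattic_pre"]), 2)
})

test_that("replicate noise reproduces the configured class sd", {
  s <- generate_suite(REF, seed = 9, replicates = 1000, network = NET)
  one <- s[s$experiment == "tc40" & s$observable == "pSTAT3" &
             abs(s$time_h - 0.5) < 1e-9, ]
  expect_equal(nrow(one), 1000L)
  expect_lt(abs(stats::sd(one$value) - REF$noise[["immunoblot"]]) /
              REF$noise[["immunoblot"]], 0.05)
})

test_that("noise-free generation returns exact model predictions", {
  s <- generate_suite(REF, noise = c(massspec = 0), seed = 1,
                      replicates = 1, network = NET)
  deg <- s$value[s$observable == "phospho_degree"]
  tr <- simulate_protocol(NET, PVEC, stimulation_protocol(40, c(0, 18 / 60)))
  expect_equal(deg, phospho_degree(tr, 18 / 60), tolerance = 1e-9)
})

test_that("in-vivo serum pulses match their specification", {
  iv <- generate_invivo(REF, n = 10000, seed = 21, times = c(2, 24))
  serum <- iv$serum
  m <- function(cond, tt) mean(serum$value[serum$condition == cond &
                                             serum$time_h == tt])
  expect_lt(abs(m("LPS", 2) - 201.8) / 201.8, 0.03)
  expect_lt(abs(m("PHx", 2) - 1.4) / 1.4, 0.03)
  # saline control stays below 0.1 ng/mL in every draw
  expect_lt(max(serum$value[serum$condition == "NaCl"]), 0.1)
  # return to near-baseline by 24 h
  expect_lt(m("LPS", 24), 0.05)
  expect_lt(m("PHx", 24), 0.05)
  # PHx mean clearly above Sham at the peak
  expect_gt(m("PHx", 2), m("Sham", 2))
  expect_identical(generate_invivo(REF, n = 10, seed = 3),
                   generate_invivo(REF, n = 10, seed = 3))
  expect_error(generate_invivo(REF, conditions = "Zap"), "invalid condition")
  expect_error(generate_invivo(REF, n = 0), ">= 1")
})

test_that("physiology round-trip recovers the PHx local interval", {
  ex <- generate_exvivo_curve(REF, seed = 13)
  fit <- fit_hill4(ex$dose, ex$signal)
  expect_true(fit$reliable)
  iv <- generate_invivo(REF, n = 6, seed = 13)
  phx <- iv$liver[iv$liver$condition == "PHx" & iv$liver$time_h == 2, ]
  inv <- invert_signal(fit, mean(phx$value),
                       stats::sd(phx$value) / sqrt(nrow(phx)))
  expect_lte(inv$lower, 7.4)
  expect_gte(inv$upper, 7.4)
})

test_that("LPS liver signals saturate the reference curve", {
  iv <- generate_invivo(REF, n = 6, seed = 14)
  lps <- iv$liver[iv$liver$condition == "LPS" & iv$liver$time_h == 1, ]
  h <- REF$hill
  expect_gt(mean(lps$value), 0.9 * h[["y_max"]])
})
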