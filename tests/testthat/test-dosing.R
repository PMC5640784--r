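test_that("top-up restores the bolus level exactly", {
  k <- REF$core[["k_rux_deg"]]
  topup <- compute_topup(500, k, 8)
  expect_equal(round(topup), 191)
  sched <- rux_schedule(c(0, 8, 16), c(500, topup, topup))
  conc <- inhibitor_profile(sched, k)
  eps <- 1e-9
  expect_equal(conc(0 + eps), 500, tolerance = 1e-6)
  expect_equal(conc(8 + eps), 500, tolerance = 1e-6)
  expect_equal(conc(16 + eps), 500, tolerance = 1e-6)
  expect_error(compute_topup(-1, k, 8), "positive")
  expect_error(compute_topup(500, k, 0), "positive")
})

test_that("schedule construction enforces the dose limit", {
  expect_error(rux_schedule(c(0, 4, 8, 12), rep(100, 4)), "at most 3")
  expect_error(rux_schedule(0, -5), "negative")
  s <- rux_schedule(c(8, 0), c(191, 500))
  expect_equal(s$times, c(0, 8))    # sorted
  expect_equal(s$doses, c(500, 191))
})

test_that("reference Triple schedule matches 500/191/191 at 0/8/16", {
  tri <- reference_schedules()$Triple
  expect_equal(tri$times, c(0, 8, 16))
  expect_equal(tri$doses, c(500, 191, 191))
})

test_that("species scaling divides doses by the factor (mouse -> human)", {
  tri <- reference_schedules()$Triple
  hum <- scale_for_species(tri, 10)
  expect_equal(hum$doses, c(50, 19, 19))
  back <- scale_for_species(hum, 1 / 10)
  expect_true(all(abs(back$doses - tri$doses) <= 1))
  expect_error(scale_for_species(tri, 0), "> 0")
})

test_that("cap violations are rejected before simulating", {
  over <- rux_schedule(c(0, 1), c(400, 400), cap = 500)
  expect_error(evaluate_schedule(NET, PVEC, over), "exceeds cap")
})

test_that("the Triple schedule dominates the Single for every gene", {
  sch <- reference_schedules()
  ev_tri <- evaluate_schedule(NET, PVEC, sch$Triple)
  ev_sin <- evaluate_schedule(NET, PVEC, sch$Single)
  expect_identical(ev_tri$gene, ev_sin$gene)
  expect_true(all(ev_tri$integral_normalized < ev_sin$integral_normalized))
  # the inhibitor only suppresses, never boosts, the response
  expect_true(all(ev_tri$integral_normalized > 0))
  expect_true(all(ev_tri$integral_normalized < 1))
})

test_that("design_schedule prefers repeated dosing under the cap", {
  des <- design_schedule(NET, PVEC, cap = 500, max_doses = 3,
                         bolus_times = 0, bolus_grid = 1)
  expect_length(des$best$times, 3L)
  conc <- inhibitor_profile(des$best, PVEC[["k_rux_deg"]])
  expect_true(all(conc(seq(0, 24, by = 0.1)) <= 500 * (1 + 1e-9)))
  expect_equal(min(des$curves$objective),
               des$curves$objective[des$curves$n_doses == 3])
})

test_that("human-scaled parameters halve the response near 50 nM", {
  ref_h <- reference_parameters(mode = "human")
  expect_equal(ref_h$core[["Ki_rux"]], REF$core[["Ki_rux"]] / 10)
  core_h <- build_core_model(ref_h$core, ref_h$compartments,
                             ref_h$fixed_totals)
  ic_h <- ic50(core_h, ref_h$core, il6 = 40,
               doses = 10^seq(0, 3, length.out = 13))
  expect_lt(abs(ic_h - 50) / 50, 0.1)
})

test_that("ic50 demands a monotone, bracketing dose grid", {
  expect_error(ic50(CORE_NET, REF$core, doses = c(1, 2)), "bracket")
})
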