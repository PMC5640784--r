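test_that("dose event validation", {
  expect_error(dose_event(0, "Ruxolitinib", 500, "set"), "add")
  expect_error(dose_event(0, "Stattic", 100, "add"), "set")
  expect_error(dose_event(0, "ActD", 1, "wash"), "set")
  expect_error(dose_event(0, "Ruxolitinib", 1, "wash"), "add")
  expect_error(dose_event(0, "IL6", -1), ">= 0")
  expect_error(dose_event(0, "Interferon", 1), "arg")
})

test_that("unstimulated steady state: basal activation, small but nonzero", {
  ss <- equilibrate(CORE_NET, REF$core)
  expect_gt(ss[["pSTAT3"]], 0)
  expect_gt(ss[["SOCS3"]], 0)
  expect_lt(ss[["pSTAT3"]], 0.05 * ss[["STAT3"]])
  dyn <- !grepl("^IntRNA_", names(ss))
  parms <- c(as.list(REF$core), list(IL6 = 0, Stattic = 0, ActD = 0))
  net <- compile_network(CORE_NET)
  dy <- net$compiled$rhs(0, ss, parms)[[1]]
  expect_lt(max(abs(dy[dyn])), 1e-9)
})

test_that("integration and root solving find the same steady state", {
  ss1 <- equilibrate(NET, PVEC, method = "integrate")
  ss2 <- equilibrate(NET, PVEC, method = "root")
  keep <- ss1 > 1e-9
  expect_equal(ss2[keep] / ss1[keep], rep(1, sum(keep)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("total STAT3 amount is conserved across dose events", {
  grid <- seq(0, 4, by = 0.05)
  protocols <- list(
    stimulation_protocol(40, grid),
    protocol(rbind(dose_event(-1, "Ruxolitinib", 500, "add"),
                   dose_event(0, "IL6", 40, "set"),
                   dose_event(1, "IL6", 0, "wash"),
                   dose_event(2, "ActD", 1, "set")),
             grid)
  )
  for (pr in protocols) {
    tr <- simulate_protocol(NET, PVEC, pr)
    amt <- stat3_amount(tr)
    expect_equal(amt / amt[1], rep(1, length(amt)), tolerance = 1e-7)
  }
})

test_that("simulated Ruxolitinib state matches the closed form", {
  sched <- reference_schedules()$Triple
  pr <- protocol(rbind(dose_event(0, "IL6", 40, "set"),
                       dose_event(0, "Ruxolitinib", 500, "add"),
                       dose_event(8, "Ruxolitinib", 191, "add"),
                       dose_event(16, "Ruxolitinib", 191, "add")),
                 seq(0.5, 23.5, by = 0.5))
  tr <- simulate_protocol(NET, PVEC, pr)
  conc <- inhibitor_profile(sched, PVEC[["k_rux_deg"]])
  expect_equal(tr$states[, "Rux"], conc(tr$times),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("observables are robust to 100x tighter solver tolerances", {
  pr <- stimulation_protocol(40, c(0.1, 0.3, 0.5, 1, 2, 6, 24))
  tr1 <- simulate_protocol(NET, PVEC, pr)
  tr2 <- simulate_protocol(NET, PVEC, pr, rtol = 1e-10, atol = 1e-14)
  for (on in c("pSTAT3", "Socs3RNA", "SOCS3", "AppRNA_Fgg", "nSTAT3")) {
    a <- tr1$states[, on]; b <- tr2$states[, on]
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-3)
  }
})

test_that("IL-6 wash terminates signalling", {
  grid <- seq(0, 3, by = 0.05)
  tr_cont <- simulate_protocol(NET, PVEC, stimulation_protocol(40, grid))
  tr_pulse <- simulate_protocol(
    NET, PVEC,
    protocol(rbind(dose_event(0, "IL6", 40, "set"),
                   dose_event(0.5, "IL6", 0, "wash")), grid))
  ps_c <- trajectory_states(tr_cont, 3)[, "pSTAT3"]
  ps_p <- trajectory_states(tr_pulse, 3)[, "pSTAT3"]
  expect_lt(ps_p, 0.2 * ps_c)
})

test_that("trajectory interpolation rejects out-of-span times", {
  tr <- simulate_protocol(NET, PVEC, stimulation_protocol(40, c(0, 1)))
  expect_error(trajectory_states(tr, 2), "outside")
  expect_error(trajectory_states(tr, -1), "outside")
})

test_that("states stay non-negative under strong stimulation", {
  pr <- stimulation_protocol(500, seq(0, 24, by = 0.1))
  tr <- simulate_protocol(NET, PVEC, pr)
  expect_true(all(tr$states > -1e-9))
})
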