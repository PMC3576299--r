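# Integration engine: steady baseline, event handling, determinism,
# solver convergence, and outcome summaries.

p <- apap_parameters()
g <- gsh_parameters()

test_that("an empty protocol stays at baseline for 48 h", {
  tr <- simulate_protocol(dosing_protocol(horizon = 48), p, g)
  apap_vars <- c("gapap", "papap", "lapap", "tapap", "uapap", "lnq", "lcov")
  for (v in apap_vars) expect_lt(max(abs(tr[[v]])), 1e-6)
  expect_lt(max(abs(tr$lgsh / g$lgsh_baseline - 1)), 0.001)
  expect_equal(tr$hep_frac, rep(1, nrow(tr)), tolerance = 1e-6)
  # sampling contract: at least 10 samples per hour
  expect_gte(nrow(tr), 480)
  expect_true(all(diff(tr$time) > 0))
})

test_that("a therapeutic bolus gives a single-peaked plasma APAP curve", {
  tr <- run_therapeutic()
  i_peak <- which.max(tr$papap)
  expect_gt(tr$papap[i_peak], 50)          # clearly nonzero peak
  expect_gt(tr$time[i_peak], 0.2)          # absorption takes some time
  expect_lt(tr$time[i_peak], 6)
  # unimodal: nondecreasing before the peak, nonincreasing after
  # (tolerate solver-level wiggles of < 0.1% of the peak)
  tol <- 1e-3 * tr$papap[i_peak]
  expect_true(all(diff(tr$papap[1:i_peak]) > -tol))
  expect_true(all(diff(tr$papap[i_peak:nrow(tr)]) < tol))
})

test_that("identical inputs give bit-identical trajectories", {
  pr <- oral_dose(5000, horizon = 24)
  t1 <- simulate_protocol(pr, p, g)
  t2 <- simulate_protocol(pr, p, g)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("non-jumped variables are continuous across dose events", {
  pr <- build_chronic_regimen(1000, 6, 0.5)  # boluses at 0 and 6 hr
  tr <- simulate_protocol(pr, p, g)
  # inspect the neighborhood of the 6 hr bolus: plasma and liver series
  # move by o(dt) across the event while the gut jumps (the grid stores the
  # pre-jump state at the event time; the next point is post-jump)
  i <- max(which(tr$time <= 6 + 1e-9))
  j <- i + 1L  # first point after the event
  expect_gt(tr$gapap[j] - tr$gapap[i], 1000)      # gut jump
  # slowly-responding pools barely move over the post-event step
  for (v in c("lgsh", "fh"))
    expect_lt(abs(tr[[v]][j] - tr[[v]][i]),
              1e-2 * max(abs(tr[[v]])) + 1e-6)

  # an infusion window edge introduces no jump in any state variable: the
  # step across the event is comparable to the neighboring ordinary steps
  pr2 <- dosing_protocol(nac_protocol(1, 6), horizon = 12)
  tr2 <- simulate_protocol(pr2, p, g)
  i2 <- max(which(tr2$time <= 6 + 1e-9))
  for (v in apapsim:::state_names) {
    x <- tr2[[v]]
    step_event <- abs(x[i2 + 1L] - x[i2])
    step_next <- abs(x[i2 + 2L] - x[i2 + 1L])
    expect_lt(step_event, 3 * step_next + 1e-3 * max(abs(x), 1e-6) + 1e-9)
  }
})

test_that("halving solver tolerances barely moves the 22 g outcome", {
  pr <- oral_dose(22000, horizon = 72)
  a <- simulate_protocol(pr, p, g, rtol = 1e-6, atol = 1e-9)
  b <- simulate_protocol(pr, p, g, rtol = 5e-7, atol = 5e-10)
  expect_lt(abs(min(a$hep_frac) - min(b$hep_frac)), 1e-4)
})

test_that("summaries classify outcomes at the 30% hepatocyte threshold", {
  tr <- run_therapeutic()
  s <- summarize_trajectory(tr)
  expect_equal(s$outcome, "recovery")
  expect_gt(s$min_hep_frac, 0.9)
  expect_lt(s$gsh_nadir_pct, 100)

  tr22 <- run_22g()
  s22 <- summarize_trajectory(tr22)
  expect_equal(s22$outcome, "death")
  expect_lt(s22$min_hep_frac, 0.30)

  # threshold semantics: the same trajectory flips label with the threshold
  s_lo <- summarize_trajectory(tr22, death_threshold = 1e-6)
  expect_equal(s_lo$outcome, "recovery")

  expect_error(summarize_trajectory(
    simulate_protocol(oral_dose(100, horizon = 12), p, g)), "48")
})

test_that("urinary totals follow the trajectory and respect mass bounds", {
  tr <- run_therapeutic()
  s <- summarize_trajectory(tr)
  u <- s$urinary_24h_mmol
  expect_true(all(u > 0))
  # cannot exceed absorbed dose: 1000 mg * 0.75 / 151.16 = 4.96 mmol
  expect_lt(sum(u), 1000 * 0.75 / 151.16)
  # glucuronide dominates sulfate at therapeutic doses (PAPS-limited SULT)
  expect_gt(u[["uag"]], u[["uas"]])
})

test_that("hepatocyte fraction keeps declining for a while after NAC starts", {
  tr <- run_22g_nac(1)
  # rescue at 2 h: the minimum is reached well after the infusion ends
  i_min <- which.min(tr$hep_frac)
  expect_gt(tr$time[i_min], 5)
  expect_lt(at_time(tr, "hep_frac", 10), at_time(tr, "hep_frac", 4))
})
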