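# Glutathione surrogate: baseline equilibrium, stability, NAC response,
# dose monotonicity, and the shipped calibration contract.

p <- apap_parameters()
g <- gsh_parameters()

test_that("submodel contributions vanish at the drug-free baseline", {
  s0 <- baseline_state(p, g)
  terms <- gsh_rhs_terms(s0, p, g)
  expect_equal(terms$dlgsh, 0, tolerance = 1e-6 * g$lgsh_baseline)
  expect_equal(terms$dpgsh, 0, tolerance = 1e-8)
  expect_equal(terms$dlcys, 0, tolerance = 1e-8)
  expect_equal(terms$dpnac, 0)
  expect_equal(terms$v_gst, 0)
  # derived members satisfy the stated steady-state identities
  turnover <- g$k_gsh_deg * g$lgsh_baseline +
    g$V_gsh_export * g$lgsh_baseline / (g$Km_gsh_export + g$lgsh_baseline)
  expect_equal(terms$v_syn, turnover, tolerance = 1e-10)
})

test_that("the baseline is locally stable: GSH perturbations decay", {
  for (f in c(0.9, 1.1)) {
    s <- baseline_state(p, g)
    s["lgsh"] <- f * g$lgsh_baseline
    sol <- deSolve::lsoda(s, c(0, 100, 250), apap_rhs,
                          list(params = p, gsh = g),
                          rtol = 1e-8, atol = 1e-8)
    dev0 <- abs(f - 1)
    dev1 <- abs(sol[3, "lgsh"] / g$lgsh_baseline - 1)
    expect_lt(dev1, dev0 / 2)
  }
})

test_that("NAC supplies cysteine and raises the GSH trajectory", {
  # mechanism: plasma NAC feeds the cysteine pool and is cleared
  s <- baseline_state(p, g)
  s["pnac"] <- 1000
  terms <- gsh_rhs_terms(s, p, g)
  base_terms <- gsh_rhs_terms(baseline_state(p, g), p, g)
  expect_gt(terms$dlcys, base_terms$dlcys)
  expect_lt(terms$dpnac, 0)

  # dynamics: under a 22 g overdose, NAC rescue keeps liver GSH at or above
  # the unrescued trajectory at all times after the infusion starts
  tr0 <- run_22g()
  tr1 <- run_22g_nac(1)
  tt <- seq(3, 90, by = 1)
  g0 <- vapply(tt, function(t) at_time(tr0, "lgsh", t), numeric(1))
  g1 <- vapply(tt, function(t) at_time(tr1, "lgsh", t), numeric(1))
  expect_true(all(g1 >= g0 - 1e-6))
  expect_gt(max(g1 - g0), 100)
})

test_that("pnac = 0 reduces the submodel to autonomous GSH turnover", {
  s <- baseline_state(p, g)
  s["lgsh"] <- 3000
  t1 <- gsh_rhs_terms(s, p, g, nac_rate = 0)
  expect_equal(t1$dpnac, 0)
  # lcys dynamics then involve only supply, catabolism and synthesis
  expect_equal(t1$dlcys,
               g$J_cys - g$k_cys_clear * s[["lcys"]] *
                 (1 + s[["lcys"]] / g$Km_cys_catab) - t1$v_syn,
               tolerance = 1e-10)
})

test_that("conjugation at synthesis capacity prevents GSH from rising", {
  # choose NAPQI so that V_GST equals the current synthesis flux
  s <- baseline_state(p, g)
  s["lgsh"] <- 350  # deep depletion
  syn <- gsh_rhs_terms(s, p, g)$v_syn
  gshfac <- s[["lgsh"]] / (p$Km_gst_gsh + s[["lgsh"]])
  lnq <- stats::uniroot(function(x)
    p$Vmax_gst * x / (p$Km_gst_napqi + x) * gshfac - syn,
    c(1e-9, 1e6))$root
  s["lnq"] <- lnq
  terms <- gsh_rhs_terms(s, p, g)
  expect_lte(terms$dlgsh, 0)
})

test_that("GSH nadir is monotone decreasing in APAP dose", {
  doses <- c(1, 5, 10, 15, 20) * 1000
  nadir <- vapply(doses, function(d) {
    tr <- simulate_protocol(oral_dose(d, horizon = 48), p, g)
    min(tr$lgsh)
  }, numeric(1))
  expect_true(all(diff(nadir) < 0))
})

test_that("the shipped defaults pass the calibration targets", {
  m <- gsh_calibration_metrics(g, p)
  targets <- gsh_calibration_targets()
  for (nm in names(targets)) {
    expect_gte(m[[nm]], targets[[nm]][1])
    expect_lte(m[[nm]], targets[[nm]][2])
  }
  # gsh_calibrate() accepts them without refinement
  expect_no_error(gsh_calibrate(g, p))
})

test_that("infeasible calibration targets raise an error naming the target", {
  bad <- gsh_calibration_targets()
  bad$overdose15_nadir_pct <- c(99, 100)  # a 15 g dose cannot leave 99% GSH
  expect_error(gsh_calibrate(g, p, targets = bad), "overdose15_nadir_pct")
})

test_that("baseline hepatic GSH sits near the GST Km as the kinetics require", {
  # several-mM GSH half-saturates GST (Km 5200 uM), so conjugation capacity
  # degrades roughly in proportion to depletion
  expect_gt(g$lgsh_baseline / (g$lgsh_baseline + p$Km_gst_gsh), 0.4)
  expect_lt(g$lgsh_baseline / (g$lgsh_baseline + p$Km_gst_gsh), 0.8)
})
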