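# Closed-form oracles for the four hepatic rate laws. Expected values are
# frozen from independent hand evaluation of the published kinetic forms
# (Michaelis-Menten arithmetic done term by term, not through the package).

p <- apap_parameters()

test_that("P450 velocity matches hand-evaluated Michaelis-Menten + activation", {
  expect_equal(v_cyp_total(0, p), 0)

  # at 677 uM (CYP2E1 half-saturation):
  #   2E1: 345*677/1354 = 172.5; 1A2: 0.55*677/4107 = 0.090662;
  #   3A4: 0.99*677/953 = 0.703305
  #   activation: 1 + 20*677^2/(18000^2 + 677^2) = 1.0282486
  mm <- 345 * 677 / (677 + 677) + 0.55 * 677 / (3430 + 677) +
    0.99 * 677 / (276 + 677)
  act <- 1 + 20 * 677^2 / (18000^2 + 677^2)
  expect_equal(v_cyp_total(677, p), mm * act, tolerance = 1e-12)
  expect_equal(v_cyp_total(677, p), 178.19, tolerance = 1e-4)

  # saturation limit: (0.55 + 345 + 0.99) * (1 + 20) = 7277.34
  expect_equal(v_cyp_total(1e14, p), 7277.34, tolerance = 1e-6)

  # monotone nondecreasing and bounded
  s <- c(0, 10^(0:7))
  v <- v_cyp_total(s, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 346.54 * 21 + 1e-9))

  # cyp_fold scales the whole flux
  p2 <- apap_parameters(cyp_fold = 2)
  expect_equal(v_cyp_total(677, p2), 2 * v_cyp_total(677, p))

  expect_error(v_cyp_total(-1, p), "nonnegative")
})

test_that("UGT isoform kinetics: half-saturation, substrate inhibition, Hill", {
  expect_equal(v_ugt_total(0, p, "liver"), 0)

  # isolate isoform 3 (Michaelis-Menten) at its Km: exactly Vmax3/2
  p3 <- apap_parameters(Vmax_ugt_liver = c(1e-12, 1e-12, 4900, 1e-12))
  expect_equal(v_ugt_total(9200, p3, "liver"), 2450, tolerance = 1e-6)

  # isolate isoform 2 (substrate inhibition) at 4000 uM:
  #   490*4000/(4000 + 4000*(1 + 4000/23000)) = 225.3731...
  p2i <- apap_parameters(Vmax_ugt_liver = c(1e-12, 490, 1e-12, 1e-12))
  expect_equal(v_ugt_total(4000, p2i, "liver"),
               490 * 4000 / (4000 + 4000 * (1 + 4000 / 23000)),
               tolerance = 1e-9)
  expect_equal(v_ugt_total(4000, p2i, "liver"), 225.40, tolerance = 1e-4)

  # substrate-inhibited isoforms are unimodal with max at sqrt(Km*Ki)
  s_star <- sqrt(4000 * 23000)
  s <- seq(1000, 60000, by = 500)
  v2 <- v_ugt_total(s, p2i, "liver")
  expect_lt(abs(s[which.max(v2)] - s_star), 1000)
  expect_true(all(diff(v2[s < s_star - 500]) > 0))
  expect_true(all(diff(v2[s > s_star + 500]) < 0))
  # -> 0 as S -> Inf
  expect_lt(v_ugt_total(1e9, p2i, "liver"), 0.02)

  # tissue Vmax is exactly 20% of liver
  expect_equal(v_ugt_total(2500, p, "tissue") / v_ugt_total(2500, p, "liver"),
               0.2, tolerance = 1e-12)

  expect_error(v_ugt_total(-0.1, p, "liver"), "nonnegative")
  expect_error(v_ugt_total(100, p, "muscle"))
})

test_that("SULT bi-bi kinetics saturate in both substrates", {
  expect_equal(v_sult(0, 100, p, "liver"), 0)
  expect_equal(v_sult(100, 0, p, "liver"), 0)
  # double half-saturation: Vmax/4
  expect_equal(v_sult(97, 5.6, p, "liver"), 1785 / 4, tolerance = 1e-12)
  expect_equal(v_sult(97, 5.6, p, "tissue"), 357 / 4, tolerance = 1e-12)
  # saturation limit
  expect_equal(v_sult(1e12, 1e12, p, "liver"), 1785, tolerance = 1e-6)
  expect_true(all(v_sult(10^(0:6), 30, p, "liver") <= 1785))
  expect_error(v_sult(-1, 5, p), "nonnegative")
})

test_that("GST conjugation velocity follows the two-substrate saturable form", {
  expect_equal(v_gst(0, 7000, p), 0)
  # NAPQI at Km, GSH saturated: Vmax/2
  expect_equal(v_gst(15, 1e12, p), 36000, tolerance = 1e-3)
  # both at Km: Vmax/4
  expect_equal(v_gst(15, 5200, p), 18000, tolerance = 1e-12)
  # monotone in both substrates
  expect_true(all(diff(v_gst(10^(0:5), 5000, p)) > 0))
  expect_true(all(diff(v_gst(5, 10^(0:5), p)) > 0))
  expect_error(v_gst(1, -1, p), "nonnegative")
})

test_that("all rate laws vanish at zero substrate", {
  expect_equal(v_cyp_total(0, p), 0)
  expect_equal(v_ugt_total(0, p, "liver"), 0)
  expect_equal(v_ugt_total(0, p, "tissue"), 0)
  expect_equal(v_sult(0, 0, p, "liver"), 0)
  expect_equal(v_gst(0, 0, p), 0)
})
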