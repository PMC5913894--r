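test_that("LQ fractionation normalization has the right fixed points", {
  kp <- ntcp_params("kidney")
  # 37.5 Gy in 25 fractions is exactly 1.5 Gy/fraction: unchanged
  expect_equal(eqd_normalize(37.5, kp), 37.5)
  expect_equal(eqd_normalize(0, kp), 0)
  expect_equal(eqd_normalize(45, kp), 45 * (45 / 25 + 2.5) / (1.5 + 2.5),
               tolerance = 1e-12)
})

test_that("LKB model hits its analytic anchor points", {
  kid <- ntcp_params("kidney")
  liv <- ntcp_params("liver")
  expect_equal(kid$TD50_5, 12); expect_equal(kid$n, 0.70)
  expect_equal(kid$m, 0.26)
  expect_equal(liv$TD50_5, 30); expect_equal(liv$n, 0.32)
  expect_equal(liv$m, 0.15)

  # whole organ exactly at tolerance: 50% complication probability
  expect_equal(lkb_ntcp(make_synthetic_dvh(150, c(0, 12), c(1, 1)), kid),
               0.5, tolerance = 1e-12)
  expect_equal(lkb_ntcp(make_synthetic_dvh(1500, c(0, 30), c(1, 1)), liv),
               0.5, tolerance = 1e-12)

  # one slope unit above tolerance: probit identity Phi(1)
  d1 <- 12 * (1 + 0.26)
  expect_equal(lkb_ntcp(make_synthetic_dvh(150, c(0, d1), c(1, 1)), kid),
               stats::pnorm(1), tolerance = 1e-12)

  # half the liver at 30 Gy: effective dose reduced by the volume exponent
  half <- make_synthetic_dvh(1500, c(0, 30), c(1, 0.5))
  d_eff <- 30 * 0.5^0.32
  expect_equal(lkb_ntcp(half, liv),
               stats::pnorm((d_eff - 30) / (0.15 * 30)), tolerance = 1e-12)
})

test_that("volume-exponent limits recover mean and maximum dose", {
  dvh <- make_synthetic_dvh(100, c(0, 10, 20, 40), c(1, 0.7, 0.3, 0.1))
  dd <- wishplan:::dvh_differential(dvh)
  mean_d <- sum(dd$dose * dd$mass)
  p_mean <- ntcp_params(TD50_5 = 30, m = 0.2, n = 0.999)
  p_max <- ntcp_params(TD50_5 = 30, m = 0.2, n = 0.01)
  eff <- function(p) wishplan:::gen_mean(dd$dose, dd$mass, 1 / p$n)
  expect_equal(eff(p_mean), mean_d, tolerance = 1e-2)
  expect_equal(eff(p_max), max(dd$dose), tolerance = 0.5)
})

test_that("NTCP is strictly increasing in uniform dose", {
  kid <- ntcp_params("kidney")
  doses <- seq(2, 30, by = 2)
  vals <- vapply(doses, function(D)
    lkb_ntcp(make_synthetic_dvh(150, c(0, D), c(1, 1)), kid), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
})

test_that("per-organ NTCP reports scale monotonically with plan dose", {
  s <- fixture_phantom()
  p <- normalize_plan(fixture_plan(), s)
  rep1 <- organ_ntcp_report(p, s)
  expect_setequal(rep1$structure, c("KidneyL", "KidneyR", "Liver-PTV"))
  expect_true(all(rep1$ntcp_pct >= 0 & rep1$ntcp_pct <= 100))

  p_hot <- p
  p_hot$dose <- p$dose * 1.1
  rep2 <- organ_ntcp_report(p_hot, s)
  expect_true(all(rep2$ntcp_pct >= rep1$ntcp_pct - 1e-9))

  p_zero <- p
  p_zero$dose <- p$dose * 0
  rep0 <- organ_ntcp_report(p_zero, s)
  expect_true(all(rep0$ntcp_pct < 0.01))  # percent scale: < 0.01%

  # absent organ masks are reported as NA, not an error
  s2 <- s
  s2$masks[["Liver-PTV"]] <- NULL
  rep3 <- organ_ntcp_report(p, s2)
  expect_true(is.na(rep3$ntcp_pct[rep3$structure == "Liver-PTV"]))

  # voxel-wise and bin-wise fractionation correction agree closely
  rep4 <- organ_ntcp_report(p, s, binwise = TRUE)
  expect_equal(rep4$ntcp_pct, rep1$ntcp_pct, tolerance = 0.5)
})

test_that("malformed DVHs and parameters are rejected", {
  kid <- ntcp_params("kidney")
  bad <- dvh_curve(c(0, 10), c(1, 0.5))  # 50% of the organ unaccounted: ok
  expect_silent(lkb_ntcp(bad, kid))      # residual mass sits at the max dose
  expect_error(ntcp_params(TD50_5 = 10, m = 0.2, n = 1.5), "n")
  expect_error(ntcp_params("pancreas"))
  expect_error(dvh_curve(c(0, 10), c(0.9, 0.5)), "start at")
})
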