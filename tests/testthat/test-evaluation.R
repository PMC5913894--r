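test_that("exact cumulative DVHs and their inversion handle step cases", {
  dvh <- compute_dvh(rep(10, 8))
  expect_equal(dose_at_volume(dvh, 50), 10)
  expect_equal(dvh$volume[1], 1)

  dvh2 <- compute_dvh(c(0, 10, 20, 30))
  # V(15): two of four voxels at >= 15 Gy
  i <- findInterval(15, dvh2$dose)
  expect_equal(sum(c(0, 10, 20, 30) >= 15) / 4, 0.5)
  expect_equal(dose_at_volume(dvh2, 50), 20)

  # two-level DVH: half the volume at 0, half at 20
  dvh3 <- compute_dvh(c(0, 0, 20, 20))
  expect_equal(dose_at_volume(dvh3, 50), 20)
  expect_equal(dose_at_volume(dvh3, 60), 0)

  expect_error(compute_dvh(numeric(0)), "non-empty")
})

test_that("differential-DVH integration recovers the mean dose", {
  set.seed(5)
  for (rep in 1:10) {
    d <- round(runif(200, 0, 50), 2)
    expect_equal(dvh_mean_dose(compute_dvh(d)), mean(d), tolerance = 1e-9)
    nb <- 600
    bw <- max(d) / (nb - 1)
    expect_equal(dvh_mean_dose(compute_dvh(d, n_bins = nb)), mean(d),
                 tolerance = bw)
  }
})

test_that("binned DVH metrics agree with order statistics within a bin", {
  set.seed(6)
  for (rep in 1:10) {
    d <- runif(300, 0, 60)
    nb <- 1201
    bw <- max(d) / (nb - 1)
    dvh <- compute_dvh(d, n_bins = nb)
    for (q in c(2, 30, 50, 60, 98)) {
      direct <- dvh_direct_stat(d, q)
      expect_lt(abs(dose_at_volume(dvh, q) - direct), bw + 1e-9)
      # and the exact curve reproduces the order statistic itself
      expect_equal(dose_at_volume(compute_dvh(d), q), direct,
                   tolerance = 1e-12)
    }
    expect_lte(dose_at_volume(dvh, 98), dose_at_volume(dvh, 50) + 1e-9)
    expect_lte(dose_at_volume(dvh, 50), dose_at_volume(dvh, 2) + 1e-9)
  }
})

test_that("synthetic DVHs validate their inputs and integrate correctly", {
  dvh <- make_synthetic_dvh(100, c(0, 12), c(1, 1))
  expect_equal(dvh_mean_dose(dvh), 12)
  expect_equal(dose_at_volume(dvh, 50), 12)

  half <- make_synthetic_dvh(200, c(0, 30), c(1, 0.5))
  expect_equal(dvh_mean_dose(half), 15)

  expect_error(make_synthetic_dvh(100, numeric(0), numeric(0)), "non-empty")
  expect_error(make_synthetic_dvh(100, c(0, 10), c(0.8, 0.5)), "start at 1")
  expect_error(make_synthetic_dvh(100, c(0, 10, 20), c(1, 0.4, 0.6)),
               "nonincreasing")
})

# a hand-made plan: linear dose ramp over a 4x4x2 body, PTV = hottest half
make_ramp_plan <- function(scale = 1) {
  grid <- voxel_grid(c(4, 4, 2), spacing = 10)
  body <- array(TRUE, dim = grid$shape)
  e <- array(FALSE, dim = grid$shape)
  ptv <- e; ptv[, , 2] <- TRUE
  one <- function(i) { m <- e; m[i, 1, 1] <- TRUE; m }
  s <- structure_set(grid, list(
    Body = body, PTV = ptv, KidneyL = one(1), KidneyR = one(2),
    Liver = one(3), SpinalCord = one(4), Heart = e | one(1), LungL = one(2),
    LungR = one(3)))
  dose <- c(seq(1, 16) * 2, seq(30, 45, length.out = 16)) * scale
  p <- structure(list(fluence = dose, dose = dose, body_idx = which(body),
                      grid = grid, provenance = "prioritized", ledger = NULL,
                      prescription_gy = 45, wishlist = NULL, options = NULL,
                      normalization = NULL),
                 class = "rt_plan")
  list(p = p, s = s)
}

test_that("plan normalization pins the PTV median at the prescription", {
  x <- make_ramp_plan()
  p1 <- normalize_plan(x$p, x$s, 45)
  d <- structure_dose(p1, x$s, "PTV")
  expect_equal(dose_at_volume(compute_dvh(d), 50), 45, tolerance = 1e-12)
  # idempotent
  p2 <- normalize_plan(p1, x$s, 45)
  expect_equal(p2$dose, p1$dose, tolerance = 1e-12)
  # all other dose metrics scale by the same factor
  f <- p1$normalization$factor
  expect_equal(max(p1$dose), f * max(x$p$dose), tolerance = 1e-12)
  expect_equal(mean(structure_dose(p1, x$s, "Body")),
               f * mean(structure_dose(x$p, x$s, "Body")),
               tolerance = 1e-12)
})

test_that("homogeneity and conformity indices match their closed forms", {
  expect_equal(homogeneity_index(45, 45, 45), 0)
  expect_equal(homogeneity_index(46.3, 42.5, 45), 3.8 / 45)
  # HI is invariant under uniform rescaling
  expect_equal(homogeneity_index(46.3 * 1.1, 42.5 * 1.1, 45 * 1.1),
               homogeneity_index(46.3, 42.5, 45))
  expect_equal(conformity_index(100, 100, 100), 1)
  expect_equal(conformity_index(100, 95, 110), 95^2 / 11000)
  expect_error(conformity_index(0, 0, 10), "positive")
  expect_error(conformity_index(10, 12, 11), "exceed")
  set.seed(7)
  for (rep in 1:10) {
    TV <- runif(1, 50, 200); V <- runif(1, 50, 200)
    TVRI <- runif(1, 0, min(TV, V))
    expect_lte(conformity_index(TV, TVRI, V), 1)
  }
})

test_that("integral-dose summaries nest across thresholds", {
  x <- make_ramp_plan()
  ids <- integral_dose_summary(x$p, x$s)
  v <- ids$value[match(c("V_5Gy_pct", "V_11.25Gy_pct", "V_22.5Gy_pct"),
                       ids$metric)]
  expect_true(all(diff(v) <= 0))
  zero <- x; zero$p$dose <- zero$p$dose * 0
  ids0 <- integral_dose_summary(zero$p, zero$s, c(5, 11.25, 22.5))
  expect_equal(ids0$value[ids0$metric != "V_5Gy_pct" |
                            TRUE][1], 0)  # mean dose of a zero plan
  expect_equal(ids0$value[1], 0)
})

test_that("plan_metrics emits the full comparison row set", {
  s <- fixture_phantom()
  p <- fixture_plan()
  pn <- normalize_plan(p, s)
  m <- plan_metrics(pn, s)
  expect_true(all(c("PTV", "KidneyL", "KidneyR", "Liver-PTV", "Heart",
                    "SpinalCord", "LungL", "LungR", "Body") %in% m$structure))
  expect_true(all(c("V_95pct_pct", "D_98pct_Gy", "D_2pct_Gy", "HI", "CI")
                  %in% m$metric[m$structure == "PTV"]))
  hi <- m$value[m$structure == "PTV" & m$metric == "HI"]
  ci <- m$value[m$structure == "PTV" & m$metric == "CI"]
  expect_gte(hi, 0)
  expect_gt(ci, 0); expect_lte(ci, 1)
  d98 <- m$value[m$structure == "PTV" & m$metric == "D_98pct_Gy"]
  d2 <- m$value[m$structure == "PTV" & m$metric == "D_2pct_Gy"]
  expect_lte(d98, d2)
})
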