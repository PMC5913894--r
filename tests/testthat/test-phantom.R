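test_that("phantom generation is deterministic and honours mask invariants", {
  g <- voxel_grid(c(24, 24, 10), spacing = 6)
  s1 <- make_phantom(11, g)
  s2 <- make_phantom(11, g)
  expect_identical(s1$masks, s2$masks)
  s3 <- make_phantom(12, g)
  expect_false(identical(s1$masks$PTV, s3$masks$PTV))

  body <- s1$masks$Body
  for (nm in setdiff(names(s1$masks), "Body"))
    expect_true(all(!s1$masks[[nm]] | body), info = nm)
  expect_true(all(vapply(s1$masks, any, TRUE)))
  expect_false(any(s1$masks$PTV & s1$masks$KidneyL))
  expect_false(any(s1$masks$PTV & s1$masks$KidneyR))
  expect_false(any(s1$masks$KidneyL & s1$masks$KidneyR))
})

test_that("clinical-like PTV is more complex than the easy PTV", {
  g <- voxel_grid(c(24, 24, 10), spacing = 6)
  for (seed in c(1, 2, 3)) {
    hard <- make_phantom(seed, g, "clinical-like")
    easy <- make_phantom(seed, g, "easy")
    expect_gt(surface_to_volume(hard, "PTV"), surface_to_volume(easy, "PTV"))
  }
})

test_that("a grid too small to hold all structures fails explicitly", {
  expect_error(make_phantom(1, voxel_grid(c(3, 3, 2), spacing = 4)),
               "too small")
})

test_that("derived shells, skin ring and Liver-PTV obey their definitions", {
  s <- fixture_phantom()
  ptv <- s$masks$PTV
  body <- s$masks$Body
  sh3 <- s$masks[["PTV Shell 3 mm"]]
  sh18 <- s$masks[["PTV Shell 18 mm"]]
  sh39 <- s$masks[["PTV Shell 39 mm"]]
  for (m in list(sh3, sh18, sh39, s$masks$SkinRing)) {
    expect_false(any(m & ptv))
    expect_true(all(!m | body))
  }
  expect_false(any(sh3 & sh18))
  expect_false(any(sh18 & sh39))
  expect_true(any(sh3))
  # Liver-PTV plus the overlap reconstitutes the liver
  expect_identical(s$masks[["Liver-PTV"]] | (s$masks$Liver & ptv),
                   s$masks$Liver)
  expect_identical(s$masks$Kidneys, s$masks$KidneyL | s$masks$KidneyR)
})

test_that("an out-of-reach shell warns and comes back empty", {
  g <- voxel_grid(c(12, 12, 6), spacing = 6)
  s <- make_phantom(3, g)
  expect_warning(s2 <- expand_structures(s, shell_distances_mm = c(3, 500)),
                 "empty")
  expect_false(any(s2$masks[["PTV Shell 500 mm"]]))
})

test_that("shell membership matches a brute-force per-voxel distance oracle", {
  grid <- voxel_grid(c(20, 20, 20), spacing = 1)
  e <- array(FALSE, dim = grid$shape)
  ptv <- e; ptv[7:14, 7:14, 7:14] <- TRUE
  body <- array(TRUE, dim = grid$shape)
  one <- function(i) { m <- e; m[i, 1, 1] <- TRUE; m }
  s <- structure_set(grid, list(
    Body = body, PTV = ptv, KidneyL = one(1), KidneyR = one(2),
    Liver = one(3), SpinalCord = one(4), Heart = one(5), LungL = one(6),
    LungR = one(7)))
  s <- suppressWarnings(
    expand_structures(s, shell_distances_mm = 3, shell_thickness_mm = 3,
                      skin_ring_width_mm = 2))
  # oracle: per-voxel minimum Euclidean distance to any PTV voxel center,
  # written as a literal loop, then the documented half-voxel surface offset
  ctr <- which(ptv, arr.ind = TRUE) - 0.5
  half <- mean(grid$spacing) / 2
  in_shell <- function(i, j, k) {
    if (ptv[i, j, k]) return(FALSE)
    dmin <- Inf
    for (r in seq_len(nrow(ctr))) {
      dd <- sqrt((i - 0.5 - ctr[r, 1])^2 + (j - 0.5 - ctr[r, 2])^2 +
                   (k - 0.5 - ctr[r, 3])^2)
      if (dd < dmin) dmin <- dd
    }
    d <- max(0, dmin - half)
    d > 0 && d <= 3
  }
  # the shell is a thin band: check the full plane through the PTV center
  # plus a sample of off-plane voxels (the loop oracle is slow)
  shell <- s$masks[["PTV Shell 3 mm"]]
  for (i in 1:20) for (j in 1:20)
    expect_identical(shell[i, j, 10], in_shell(i, j, 10),
                     info = sprintf("voxel %d,%d,10", i, j))
  set.seed(1)
  idx <- cbind(sample(20, 60, TRUE), sample(20, 60, TRUE),
               sample(20, 60, TRUE))
  for (r in seq_len(nrow(idx)))
    expect_identical(shell[idx[r, 1], idx[r, 2], idx[r, 3]],
                     in_shell(idx[r, 1], idx[r, 2], idx[r, 3]))
})
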