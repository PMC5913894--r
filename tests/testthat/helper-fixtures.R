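# Shared fixtures, built lazily once per test session and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache, inherits = FALSE))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache, inherits = FALSE)
}

# small 3D phantom with derived structures (6 mm grid keeps the 3 mm shell
# non-empty)
fixture_phantom <- function() cached("phantom", {
  suppressWarnings(expand_structures(
    make_phantom(7, voxel_grid(c(24, 24, 10), spacing = 6))))
})

fixture_influence <- function() cached("influence", {
  make_influence(fixture_phantom(), n_beams = 7, beamlet_size_mm = 12,
                 seed = 7)
})

fixture_wishlist <- function() cached("wishlist", {
  resolve_limits(default_wishlist())
})

# one solved prioritized plan on the small phantom, reused across test files
fixture_plan <- function() cached("plan", {
  suppressWarnings(solve_prioritized(fixture_wishlist(), fixture_influence(),
                                     fixture_phantom()))
})

# slab body for influence-kernel tests: rectangular box, beams along x
fixture_slab <- function() cached("slab", {
  grid <- voxel_grid(c(30, 11, 7), spacing = 5)
  box <- array(TRUE, dim = grid$shape)
  one <- function(i, j, k) {
    m <- array(FALSE, dim = grid$shape); m[i, j, k] <- TRUE; m
  }
  structure_set(grid, list(
    Body = box, PTV = one(15, 6, 4), KidneyL = one(3, 3, 2),
    KidneyR = one(3, 9, 2), Liver = one(20, 6, 4), SpinalCord = one(25, 6, 4),
    Heart = one(10, 6, 4), LungL = one(5, 3, 6), LungR = one(5, 9, 6)))
})

# minimal single-voxel problem with a hand-made influence matrix
fixture_one_voxel <- function() {
  grid <- voxel_grid(c(1, 1, 1), spacing = 10)
  m <- array(TRUE, dim = c(1L, 1L, 1L))
  e <- array(FALSE, dim = c(1L, 1L, 1L))
  masks <- stats::setNames(rep(list(e), 9), wishplan:::REQUIRED_STRUCTURES)
  masks$Body <- m
  masks$PTV <- m
  s <- structure_set(grid, masks)
  A <- structure(list(
    A = Matrix::Matrix(1, 1, 1, sparse = TRUE),
    body_idx = 1L,
    beamlets = data.frame(beam = 1, angle_deg = 0, s_mm = 0, z_mm = 0),
    grid = grid,
    params = list(n_beams = 1, beamlet_size_mm = 10,
                  mu_attenuation_per_mm = 0.005, sigma_lateral_mm = 3,
                  seed = 1L, prune_rel = 0)),
    class = "influence_matrix")
  list(s = s, A = A)
}

# small wish-list built in code (no file): LTCP then a mean objective,
# with the PTV/Body maximum constraints
make_tiny_wishlist <- function(objectives, constraints = NULL, Dp = 45) {
  raw <- list(
    prescription = list(dose_gy = Dp, n_fractions = 25),
    relaxation = 0.03,
    constraints = constraints %||% list(
      list(volume = "PTV", kind = "maximum",
           limit = list(percent_of_prescription = 105)),
      list(volume = "Body", kind = "maximum",
           limit = list(percent_of_prescription = 105))),
    objectives = objectives)
  resolve_limits(wishplan:::as_wishlist(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct order statistic for D_q% under the >=-threshold DVH convention:
# the dose of the ceiling(n*q/100)-th hottest voxel
dvh_direct_stat <- function(d, q) {
  sort(d, decreasing = TRUE)[ceiling(length(d) * q / 100)]
}

# independent oracle: enumerate all 2^n sign patterns of the ranked absolute
# differences and compute the exact two-sided p-value for the observed V
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  Vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- as.logical(bitwAnd(rep(mask, n), 2^(seq_len(n) - 1L)))
    sum(r[signs])
  }, 0)
  p_lo <- mean(Vs <= V_obs)
  p_hi <- mean(Vs >= V_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exhaustive lexicographic grid-search oracle over 2-beamlet fluence maps.
# Phase 1 minimizes objective 1 over the feasible box; the bound rule
# (goal if met, else attained * (1 + relaxation)) is then applied and phase 2
# minimizes objective 2 under that bound. Each phase refines the grid around
# its incumbent so the final resolution is `step / 1000` of the box (w_j
# alone cannot exceed any hard cap, which bounds the box).
grid_search_lexi <- function(A, s, wl, step = 0.01) {
  rows_of <- function(nm) wishplan:::structure_rows(A, s, nm)
  hard <- lapply(wl$constraints, function(cn)
    list(rows = rows_of(cn$volume), b = cn$limit))
  wmax <- max(vapply(1:2, function(j)
    min(vapply(hard, function(h)
      h$b / max(A$A[h$rows, j]), 0)), 0))
  objs <- wl$objectives
  value_of <- function(w1, w2, k) {
    d <- as.numeric(A$A %*% c(w1, w2))
    if (!all(vapply(hard, function(h) max(d[h$rows]) <= h$b + 1e-12, TRUE)))
      return(Inf)
    wishplan:::eval_objective(objs[[k]], d[rows_of(objs[[k]]$volume)])
  }
  minimize <- function(fun, center = NULL) {
    st <- step * wmax
    lo1 <- lo2 <- 0; hi1 <- hi2 <- wmax
    best <- NULL
    for (stage in 1:4) {
      g1 <- seq(lo1, hi1, by = st); g2 <- seq(lo2, hi2, by = st)
      grid <- expand.grid(w1 = g1, w2 = g2)
      v <- mapply(fun, grid$w1, grid$w2)
      i <- which.min(v)
      best <- list(w = c(grid$w1[i], grid$w2[i]), value = v[i])
      if (!is.finite(best$value) && !is.null(center)) {
        # the feasible ridge can be thinner than the coarse grid: restart
        # the refinement around a point known to be feasible
        best <- list(w = center, value = fun(center[1], center[2]))
      }
      lo1 <- max(0, best$w[1] - 2 * st); hi1 <- best$w[1] + 2 * st
      lo2 <- max(0, best$w[2] - 2 * st); hi2 <- best$w[2] + 2 * st
      st <- st / 10
    }
    best
  }
  p1 <- minimize(function(a, b) value_of(a, b, 1))
  stopifnot(is.finite(p1$value))
  b1 <- if (p1$value <= objs[[1]]$goal) objs[[1]]$goal
        else p1$value * (1 + wl$relaxation)
  out <- list(f1 = p1$value, b1 = b1, w = p1$w, f2 = NA_real_)
  if (length(objs) > 1) {
    p2 <- minimize(function(a, b) {
      if (value_of(a, b, 1) > b1) Inf else value_of(a, b, 2)
    }, center = p1$w)
    out$f2 <- p2$value
    out$w <- p2$w
  }
  out
}
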