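#' @importFrom stats median quantile rnorm runif sd
#' @importFrom methods as is new
NULL

REQUIRED_STRUCTURES <- c("PTV", "KidneyL", "KidneyR", "Liver", "SpinalCord",
                         "Heart", "LungL", "LungR", "Body")

#' Structure set: named voxel masks on a common grid
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of logical arrays, all of the grid's shape. Must
#'   contain at least the nine anatomy masks `PTV`, `KidneyL`, `KidneyR`,
#'   `Liver`, `SpinalCord`, `Heart`, `LungL`, `LungR`, `Body`.
#' @param meta optional list of provenance metadata (seed, difficulty, ...).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks, meta = list()) {
  stopifnot(is_voxel_grid(grid), is.list(masks), !is.null(names(masks)))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(grid$shape)))
      stop("mask '", nm, "' is not a logical array of the grid shape")
  }
  missing <- setdiff(REQUIRED_STRUCTURES, names(masks))
  if (length(missing))
    stop("missing required structures: ", paste(missing, collapse = ", "))
  body <- masks$Body
  for (nm in setdiff(names(masks), "Body"))
    if (any(masks[[nm]] & !body))
      stop("mask '", nm, "' is not a subset of Body")
  if (!any(masks$PTV)) stop("PTV mask is empty")
  if (any(masks$KidneyL & masks$KidneyR))
    stop("KidneyL and KidneyR overlap")
  structure(list(grid = grid, masks = masks, meta = meta),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> on %d x %d x %d grid\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  cc <- vapply(x$masks, function(m) sum(m) * x$grid$voxel_volume_cc, 0)
  for (nm in names(cc)) cat(sprintf("  %-14s %8.1f cc\n", nm, cc[nm]))
  invisible(x)
}

#' Volume (cc) of one structure
#' @param s a [structure_set()].
#' @param name structure name.
#' @export
structure_volume_cc <- function(s, name) {
  stopifnot(inherits(s, "structure_set"), name %in% names(s$masks))
  sum(s$masks[[name]]) * s$grid$voxel_volume_cc
}

#' Normalized surface-to-volume ratio of a mask
#'
#' The exposed voxel-face surface area of the structure divided by the
#' surface area of the sphere of equal volume, `S / (36 pi V^2)^(1/3)`.
#' The normalization makes the ratio scale-invariant, so it measures shape
#' complexity: concave, multi-lobed structures score higher than compact
#' convex ones regardless of size. (Voxelized surfaces overestimate smooth
#' areas by a roughly constant factor, which cancels in comparisons.)
#'
#' @param s a [structure_set()].
#' @param name structure name.
#' @export
surface_to_volume <- function(s, name) {
  m <- s$masks[[name]]
  if (is.null(m)) stop("no structure named '", name, "'")
  sp <- s$grid$spacing
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  exposed <- function(sh, area) {
    nb <- pad[sh[[1]], sh[[2]], sh[[3]]]
    sum(ctr & !nb) * area
  }
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  S <- exposed(list(i - 1, j, k), sp[2] * sp[3]) +
    exposed(list(i + 1, j, k), sp[2] * sp[3]) +
    exposed(list(i, j - 1, k), sp[1] * sp[3]) +
    exposed(list(i, j + 1, k), sp[1] * sp[3]) +
    exposed(list(i, j, k - 1), sp[1] * sp[2]) +
    exposed(list(i, j, k + 1), sp[1] * sp[2])
  V <- sum(m) * prod(sp)
  S / (36 * pi * V^2)^(1 / 3)
}

# axis-aligned ellipsoid mask; semi-axes in mm, center relative to grid center
.ellipsoid <- function(grid, center_rel, semi) {
  ctr <- grid$origin + grid$extent_mm / 2 + center_rel
  if (grid$shape[3] == 1L) { center_rel[3] <- 0; ctr[3] <- grid$origin[3] + grid$extent_mm[3] / 2; semi[3] <- max(semi[3], grid$spacing[3]) }
  mask_from_predicate(grid, function(x, y, z)
    ((x - ctr[1]) / semi[1])^2 + ((y - ctr[2]) / semi[2])^2 +
      ((z - ctr[3]) / semi[3])^2 <= 1)
}

# dilate a mask by r mm (exact Euclidean, via distance to the mask)
.dilate <- function(grid, mask, r_mm) {
  if (!any(mask)) return(mask)
  out <- mask
  cand <- which(!mask)
  if (!length(cand)) return(out)
  d <- distance_to_mask(grid, cand, mask)
  out[cand[d <= r_mm]] <- TRUE
  out
}

#' Generate a seeded synthetic abdominal phantom
#'
#' Builds a voxelized body with the nine structures the gastric wish-list
#' refers to. The PTV emulates a postoperative gastric target: in
#' `"clinical-like"` mode it is a multi-concave union of a gastric-bed blob, a
#' para-aortic medial extension and a splenic-hilum extension, carved out
#' around the spinal cord and left kidney so that it partially wraps both; in
#' `"easy"` mode it is a single compact ellipsoid. Organ positions and sizes
#' are jittered per seed to emulate inter-patient variability. The phantom is
#' an acknowledged geometric surrogate, not an anatomical model.
#'
#' @param seed integer seed; the same seed reproduces the masks voxel for
#'   voxel.
#' @param grid a [voxel_grid()]; default 32 x 32 x 16 voxels at 6 mm.
#' @param difficulty `"clinical-like"` (default, multi-concave PTV) or
#'   `"easy"`.
#' @param jitter_mm maximum absolute seeded displacement of organ centers
#'   (uniform per axis), mm.
#' @param jitter_scale maximum relative seeded change of organ semi-axes.
#' @return A [structure_set()] containing the nine anatomy masks.
#' @examples
#' s <- make_phantom(1, voxel_grid(c(24, 24, 10), spacing = 8))
#' structure_volume_cc(s, "PTV")
#' @export
make_phantom <- function(seed, grid = voxel_grid(c(32, 32, 16), spacing = 6),
                         difficulty = c("clinical-like", "easy"),
                         jitter_mm = 5, jitter_scale = 0.08) {
  difficulty <- match.arg(difficulty)
  stopifnot(is_voxel_grid(grid))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  ext <- grid$extent_mm
  flat <- grid$shape[3] == 1L
  # helper producing jittered ellipsoids scaled to the grid extent;
  # nominal geometry is expressed in fractions of the body half-extent
  half <- ext / 2
  jit <- function() runif(3, -jitter_mm, jitter_mm)
  scl <- function() 1 + runif(3, -jitter_scale, jitter_scale)
  ell <- function(center_frac, semi_frac) {
    .ellipsoid(grid,
               center_rel = center_frac * half + jit(),
               semi = pmax(semi_frac * half * scl(), grid$spacing))
  }

  body <- .ellipsoid(grid, c(0, 0, 0), semi = c(0.92, 0.85, 0.97) * half)
  cordR <- max(0.07 * min(half[1:2]), 1.2 * max(grid$spacing[1:2]))
  cord <- {
    c0 <- c(0, -0.58, 0) * half + c(jit()[1] * 0.3, jit()[2] * 0.3, 0)
    ctr <- grid$origin + half + c0
    mask_from_predicate(grid, function(x, y, z)
      ((x - ctr[1]) / cordR)^2 + ((y - ctr[2]) / cordR)^2 <= 1)
  }
  kidL <- ell(c( 0.62, -0.42, -0.12), c(0.20, 0.24, 0.32))
  kidR <- ell(c(-0.62, -0.42, -0.12), c(0.20, 0.24, 0.32))
  liver <- ell(c(-0.38, 0.12, 0.28), c(0.55, 0.50, 0.42))
  heart <- ell(c( 0.10, 0.30, 0.72), c(0.30, 0.30, 0.30))
  lungL <- ell(c( 0.52, 0.05, 0.78), c(0.30, 0.38, 0.34))
  lungR <- ell(c(-0.52, 0.05, 0.78), c(0.30, 0.38, 0.34))

  if (difficulty == "clinical-like") {
    ptv <- ell(c(0.18, 0.10, 0.05), c(0.46, 0.40, 0.34)) |
      ell(c(0.02, -0.34, -0.08), c(0.17, 0.23, 0.40)) |
      ell(c(0.55, -0.12, 0.06), c(0.22, 0.24, 0.22))
    carve_k <- .dilate(grid, kidL, 1.2 * max(grid$spacing))
    carve_c <- .dilate(grid, cord, 1.0 * max(grid$spacing))
  } else {
    ptv <- ell(c(0.15, 0.06, 0.02), c(0.34, 0.30, 0.26))
    carve_k <- kidL
    carve_c <- cord
  }
  ptv <- ptv & !carve_k & !carve_c & !kidR

  masks <- list(PTV = ptv, KidneyL = kidL & !kidR, KidneyR = kidR,
                Liver = liver, SpinalCord = cord, Heart = heart,
                LungL = lungL, LungR = lungR, Body = body)
  masks <- lapply(masks, function(m) m & body)
  masks$Body <- body
  empty <- names(masks)[!vapply(masks, any, TRUE)]
  if (length(empty))
    stop("grid too small to place all structures; empty: ",
         paste(empty, collapse = ", "))
  if (any(masks$PTV & masks$KidneyL) || any(masks$PTV & masks$KidneyR))
    stop("internal: PTV overlaps a kidney")  # construction guarantees this

  structure_set(grid, masks,
                meta = list(seed = as.integer(seed), difficulty = difficulty,
                            jitter_mm = jitter_mm, jitter_scale = jitter_scale))
}

# save/restore .Random.seed so generators do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Add PTV shells, the skin ring and Liver-PTV to a structure set
#'
#' For each distance `r` in `shell_distances_mm`, adds a mask
#' `"PTV Shell <r> mm"`: body voxels outside the PTV whose Euclidean
#' distance to the PTV surface lies in `(r - shell_thickness_mm, r]`. Shells
#' are thin bands ending at the named distance, mirroring their use for
#' dose-gradient control. The surface distance of a voxel is its distance to
#' the nearest PTV voxel center minus half the (mean) voxel spacing — the
#' mask interface lies halfway between voxel centers — so the 3 mm shell is
#' the first voxel ring even on grids coarser than 3 mm. Also adds `"SkinRing"`, the band of body voxels
#' within `skin_ring_width_mm` of the body surface (measured inward from the
#' body contour), and the difference structure `"Liver-PTV"`, plus the
#' unions `"Kidneys"` and `"Lungs"` used by paired-organ objectives.
#'
#' @param s a [structure_set()].
#' @param shell_distances_mm positive distances (mm) naming the shells.
#' @param shell_thickness_mm band thickness (mm), default 3.
#' @param skin_ring_width_mm skin ring width (mm), default 21.
#' @return The structure set with derived masks added.
#' @export
expand_structures <- function(s, shell_distances_mm = c(3, 18, 39),
                              shell_thickness_mm = 3,
                              skin_ring_width_mm = 21) {
  stopifnot(inherits(s, "structure_set"),
            all(shell_distances_mm > 0), shell_thickness_mm > 0,
            skin_ring_width_mm > 0)
  grid <- s$grid
  body <- s$masks$Body
  ptv <- s$masks$PTV
  cand <- which(body & !ptv)
  half_vox <- mean(grid$spacing) / 2
  d_ptv <- pmax(0, distance_to_mask(grid, cand, ptv) - half_vox)
  for (r in shell_distances_mm) {
    m <- array(FALSE, dim = grid$shape)
    m[cand[d_ptv > r - shell_thickness_mm & d_ptv <= r]] <- TRUE
    if (!any(m))
      warning("shell at ", r, " mm is empty on this phantom")
    s$masks[[sprintf("PTV Shell %g mm", r)]] <- m
  }
  surf <- mask_boundary(body)
  inside <- which(body)
  d_surf <- distance_to_mask(grid, inside, surf)
  ring <- array(FALSE, dim = grid$shape)
  ring[inside[d_surf <= skin_ring_width_mm]] <- TRUE
  ring <- ring & !ptv
  s$masks[["SkinRing"]] <- ring
  s$masks[["Liver-PTV"]] <- s$masks$Liver & !ptv
  s$masks[["Kidneys"]] <- s$masks$KidneyL | s$masks$KidneyR
  s$masks[["Lungs"]] <- s$masks$LungL | s$masks$LungR
  s$meta$shells <- list(distances_mm = shell_distances_mm,
                        thickness_mm = shell_thickness_mm,
                        skin_ring_width_mm = skin_ring_width_mm)
  s
}
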