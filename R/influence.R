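#' Beamlet dose-influence matrix for equiangular coplanar beams
#'
#' Builds a nonnegative sparse matrix mapping beamlet fluence weights to dose
#' in every Body voxel, as a pencil-beam surrogate for arc delivery: beams are
#' parallel-ray and equiangular in the axial plane; each beamlet deposits
#' `exp(-mu * depth)` along its path, where depth is the distance travelled
#' inside the body from the entry surface, with a lateral profile equal to the
#' beamlet's rectangular aperture convolved with a Gaussian of standard
#' deviation `sigma_lateral_mm` (so adjacent beamlets tile to a flat field).
#' There is no build-up, scatter or heterogeneity modelling.
#'
#' @param s a [structure_set()] providing the Body mask and grid.
#' @param n_beams number of equiangular coplanar beams (>= 2).
#' @param beamlet_size_mm beamlet aperture width (square), mm.
#' @param mu_attenuation_per_mm linear attenuation coefficient, 1/mm.
#' @param sigma_lateral_mm lateral Gaussian spread, mm.
#' @param seed integer recorded in the metadata; the construction is
#'   deterministic, so identical inputs give identical matrices.
#' @param prune_rel entries below `prune_rel` times the beamlet's maximum are
#'   dropped to keep the matrix sparse.
#' @return An object of class `influence_matrix` with elements `A` (sparse
#'   dgCMatrix, rows = Body voxels, columns = beamlets), `body_idx` (array
#'   indices of the rows), `beamlets` (data.frame: beam, angle, lateral and
#'   longitudinal center), and `grid`.
#' @export
make_influence <- function(s, n_beams = 9, beamlet_size_mm = 12,
                           mu_attenuation_per_mm = 0.005,
                           sigma_lateral_mm = 3, seed = 1L,
                           prune_rel = 1e-4) {
  stopifnot(inherits(s, "structure_set"), n_beams >= 2,
            mu_attenuation_per_mm > 0, sigma_lateral_mm > 0,
            beamlet_size_mm > 0)
  grid <- s$grid
  body_idx <- which(s$masks$Body)
  xyz <- voxel_centers(grid)[body_idx, , drop = FALSE]
  nvox <- length(body_idx)
  w <- beamlet_size_mm
  sig <- sigma_lateral_mm
  mu <- mu_attenuation_per_mm
  cut <- w / 2 + 3.5 * sig
  flat <- grid$shape[3] == 1L
  profile <- function(ds) stats::pnorm((ds + w / 2) / sig) -
    stats::pnorm((ds - w / 2) / sig)

  angles <- 2 * pi * (seq_len(n_beams) - 1) / n_beams
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  blet <- list()
  col0 <- 0L
  binsz <- min(grid$spacing)
  for (k in seq_len(n_beams)) {
    u <- c(cos(angles[k]), sin(angles[k]))
    v <- c(-sin(angles[k]), cos(angles[k]))
    tt <- xyz[, 1] * u[1] + xyz[, 2] * u[2]
    sc <- xyz[, 1] * v[1] + xyz[, 2] * v[2]
    zz <- xyz[, 3]
    # depth from body entry: bin rays at voxel resolution, entry = min t
    sbin <- round(sc / binsz); zbin <- round(zz / binsz)
    key <- paste(sbin, zbin)
    entry <- stats::ave(tt, key, FUN = min)
    depth <- tt - entry
    datt <- exp(-mu * depth)

    scen <- .beamlet_centers(sc, w)
    zcen <- if (flat) 0 else .beamlet_centers(zz, w)
    sidx <- lapply(scen, function(s0) which(abs(sc - s0) <= cut))
    sval <- lapply(seq_along(scen), function(a)
      profile(sc[sidx[[a]]] - scen[a]))
    if (flat) {
      zidx <- list(seq_len(nvox)); zvalv <- list(rep(1, nvox))
    } else {
      zidx <- lapply(zcen, function(z0) which(abs(zz - z0) <= cut))
      zvalv <- lapply(seq_along(zcen), function(b)
        profile(zz[zidx[[b]]] - zcen[b]))
    }
    pmax0 <- profile(0)^ (if (flat) 1 else 2)
    any_col <- FALSE
    for (a in seq_along(scen)) for (b in seq_along(zcen)) {
      ia <- sidx[[a]]; ib <- zidx[[b]]
      common <- intersect(ia, ib)
      if (!length(common)) next
      va <- sval[[a]][match(common, ia)]
      vb <- zvalv[[b]][match(common, ib)]
      val <- datt[common] * va * vb
      keep <- val > prune_rel * pmax0
      if (!any(keep)) next
      any_col <- TRUE
      col0 <- col0 + 1L
      trip_i[[col0]] <- common[keep]
      trip_j[[col0]] <- rep.int(col0, sum(keep))
      trip_x[[col0]] <- val[keep]
      blet[[col0]] <- c(beam = k, angle_deg = angles[k] * 180 / pi,
                        s_mm = scen[a], z_mm = if (flat) NA_real_ else zcen[b])
    }
    if (!any_col)
      warning("beam ", k, " misses the body entirely; its beamlets dropped")
  }
  if (col0 == 0L) stop("no beamlet intersects the body")
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(nvox, col0))
  beamlets <- as.data.frame(do.call(rbind, blet))
  structure(list(A = A, body_idx = body_idx, beamlets = beamlets,
                 grid = grid,
                 params = list(n_beams = n_beams, beamlet_size_mm = w,
                               mu_attenuation_per_mm = mu,
                               sigma_lateral_mm = sig, seed = as.integer(seed),
                               prune_rel = prune_rel)),
            class = "influence_matrix")
}

.beamlet_centers <- function(coord, w) {
  lo <- min(coord); hi <- max(coord)
  n <- max(1L, ceiling((hi - lo) / w))
  mid <- (lo + hi) / 2
  mid + (seq_len(n) - (n + 1) / 2) * w
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf(
    "<influence_matrix> %d body voxels x %d beamlets (%d beams), %.2f%% dense\n",
    nrow(x$A), ncol(x$A), x$params$n_beams,
    100 * Matrix::nnzero(x$A) / prod(dim(x$A))))
  invisible(x)
}

#' Dose vector from fluence weights
#'
#' @param infl an [make_influence()] result.
#' @param fluence nonnegative numeric vector, one weight per beamlet.
#' @return numeric dose (Gy) per Body voxel (same order as `infl$body_idx`).
#' @export
influence_dose <- function(infl, fluence) {
  stopifnot(inherits(infl, "influence_matrix"),
            length(fluence) == ncol(infl$A))
  as.numeric(infl$A %*% fluence)
}

# indices (rows of A) of a structure's voxels, given the body row mapping
structure_rows <- function(infl, s, name) {
  m <- s$masks[[name]]
  if (is.null(m)) stop("no structure named '", name, "'")
  rows <- match(which(m), infl$body_idx)
  if (anyNA(rows)) stop("structure '", name, "' has voxels outside Body")
  rows
}
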