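#' Voxel grid geometry
#'
#' A regular 3D voxel lattice on which all structure masks and dose arrays
#' live. Coordinates refer to voxel centers: the center of voxel `(i, j, k)`
#' is at `origin + (c(i, j, k) - 0.5) * spacing` (mm).
#'
#' @param shape integer vector of length 3, voxels per axis (x, y, z). A
#'   single-slice grid (`shape[3] == 1`) gives the 2D mode used for small
#'   optimizer oracle problems.
#' @param spacing numeric length 3 (or 1, recycled), mm per voxel along each
#'   axis. Must be positive.
#' @param origin numeric length 3, mm position of the grid corner.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(40, 40, 20), spacing = 5)
#' g$extent_mm
#' @export
voxel_grid <- function(shape, spacing = 5, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         extent_mm = shape * spacing,
         voxel_volume_cc = prod(spacing) / 1000),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, extent %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$extent_mm), collapse = " x ")))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Voxel-center coordinates of a grid
#'
#' @param grid a [voxel_grid()].
#' @return A matrix with one row per voxel (column-major / array order) and
#'   columns `x`, `y`, `z` in mm.
#' @keywords internal
voxel_centers <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * grid$spacing[a])
  n <- grid$shape
  cbind(
    x = rep(ax[[1]], times = n[2] * n[3]),
    y = rep(rep(ax[[2]], each = n[1]), times = n[3]),
    z = rep(ax[[3]], each = n[1] * n[2]))
}

# logical array of grid shape from a predicate on voxel-center coords
mask_from_predicate <- function(grid, pred) {
  xyz <- voxel_centers(grid)
  array(pred(xyz[, 1], xyz[, 2], xyz[, 3]), dim = grid$shape)
}

# boundary voxels of a logical array: mask voxels with a 6-neighbour outside
# the mask (or on the array edge counted as outside only if `edge_is_surface`)
mask_boundary <- function(mask, edge_is_surface = TRUE) {
  d <- dim(mask)
  pad <- array(if (edge_is_surface) FALSE else NA, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  nb[is.na(nb)] <- TRUE  # off-edge neighbours treated as inside
  ctr & !nb
}

#' Euclidean distance from query voxels to the nearest voxel of a mask
#'
#' Exact nearest-neighbour distance between voxel centers, in mm, honouring
#' anisotropic spacing. Used for PTV shells and the skin ring.
#'
#' @param grid a [voxel_grid()].
#' @param query_idx integer vector of (array) voxel indices to measure from.
#' @param target_mask logical array on `grid`: the set measured to.
#' @param chunk chunk size for the vectorized search.
#' @return numeric vector of distances (mm), one per query index.
#' @keywords internal
distance_to_mask <- function(grid, query_idx, target_mask, chunk = 2048L) {
  stopifnot(any(target_mask))
  xyz <- voxel_centers(grid)
  tgt <- xyz[which(target_mask), , drop = FALSE]
  out <- numeric(length(query_idx))
  for (start in seq(1L, length(query_idx), by = chunk)) {
    ii <- query_idx[start:min(start + chunk - 1L, length(query_idx))]
    q <- xyz[ii, , drop = FALSE]
    # squared distances via the expanded inner product; exact to fp rounding
    d2 <- outer(rowSums(q^2), rowSums(tgt^2), "+") - 2 * tcrossprod(q, tgt)
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    out[start:(start + length(ii) - 1L)] <- sqrt(pmax(mins, 0))
  }
  out
}
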