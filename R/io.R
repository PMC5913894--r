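#' Serialize phantoms, influence matrices, DVHs and plans as plain text
#'
#' The on-disk container is a directory of open formats: grid and metadata as
#' JSON, masks as a CSV of voxel indices per structure, influence matrices in
#' MatrixMarket coordinate format, fluence and DVHs as CSV. Everything
#' round-trips exactly enough for reproducible re-evaluation (doses are
#' re-derived from fluence and influence, never stored).
#'
#' @param s a [structure_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @rdname serialization
#' @export
write_structure_set <- function(s, dir) {
  stopifnot(inherits(s, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(shape = s$grid$shape, spacing = s$grid$spacing,
         origin = s$grid$origin, meta = s$meta),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  idx <- do.call(rbind, lapply(names(s$masks), function(nm)
    data.frame(structure = nm, voxel = which(s$masks[[nm]]))))
  utils::write.csv(idx, file.path(dir, "masks.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname serialization
#' @param dir directory written by the corresponding writer.
#' @export
read_structure_set <- function(dir) {
  g <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- voxel_grid(g$shape, g$spacing, g$origin)
  idx <- utils::read.csv(file.path(dir, "masks.csv"))
  masks <- lapply(split(idx$voxel, idx$structure), function(v) {
    m <- array(FALSE, dim = grid$shape); m[v] <- TRUE; m
  })
  structure_set(grid, masks, meta = as.list(g$meta))
}

#' @rdname serialization
#' @param infl an [make_influence()] result.
#' @export
write_influence <- function(infl, dir) {
  stopifnot(inherits(infl, "influence_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(infl$A, file.path(dir, "influence.mtx"))
  utils::write.csv(infl$beamlets, file.path(dir, "beamlets.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(body_idx = infl$body_idx, params = infl$params,
         grid = list(shape = infl$grid$shape, spacing = infl$grid$spacing,
                     origin = infl$grid$origin)),
    file.path(dir, "influence.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname serialization
#' @export
read_influence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "influence.json"),
                              simplifyVector = TRUE)
  A <- methods::as(Matrix::readMM(file.path(dir, "influence.mtx")),
                   "CsparseMatrix")
  structure(list(A = A, body_idx = as.integer(meta$body_idx),
                 beamlets = utils::read.csv(file.path(dir, "beamlets.csv")),
                 grid = voxel_grid(meta$grid$shape, meta$grid$spacing,
                                   meta$grid$origin),
                 params = as.list(meta$params)),
            class = "influence_matrix")
}

#' @rdname serialization
#' @param dvh a [dvh_curve()].
#' @param path CSV path (columns `dose_Gy`, `volume_fraction`).
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh_curve"))
  utils::write.csv(data.frame(dose_Gy = dvh$dose,
                              volume_fraction = dvh$volume),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
read_dvh_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("dose_Gy", "volume_fraction") %in% names(x)))
    stop("DVH CSV needs columns dose_Gy, volume_fraction")
  dvh_curve(x$dose_Gy, x$volume_fraction)
}

#' @rdname serialization
#' @param p an `rt_plan`.
#' @export
write_plan <- function(p, dir) {
  stopifnot(inherits(p, "rt_plan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(beamlet = seq_along(p$fluence),
                              fluence = p$fluence),
                   file.path(dir, "fluence.csv"), row.names = FALSE)
  if (!is.null(p$ledger))
    utils::write.csv(p$ledger, file.path(dir, "ledger.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(provenance = p$provenance, prescription_gy = p$prescription_gy,
         normalization = p$normalization),
    file.path(dir, "plan.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export structure masks as NIfTI volumes
#'
#' Optional convenience requiring the RNifti package: writes one uint8 NIfTI
#' volume per mask, with the grid spacing as pixel dimensions.
#'
#' @param s a [structure_set()].
#' @param dir output directory.
#' @export
masks_to_nifti <- function(s, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("masks_to_nifti() requires the RNifti package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(s$masks)) {
    img <- RNifti::asNifti(array(as.integer(s$masks[[nm]]),
                                 dim = s$grid$shape),
                           pixdim = s$grid$spacing)
    RNifti::writeNifti(img, file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_",
                                                       nm), ".nii.gz")))
  }
  invisible(dir)
}
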