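#' Cost functions referenced by the wish-list
#'
#' Scalar plan-quality costs evaluated on a structure's voxel dose vector.
#' All weight voxels equally (masks are binary). `ltcp()` is the logarithmic
#' tumor control probability penalty, a convex exponential penalty on target
#' underdose (definition after Alber & Reemtsen); `geud()` is the generalized
#' equivalent uniform dose, the power mean of the dose vector (after Niemierko).
#'
#' @param d numeric vector of nonnegative voxel doses (Gy) of one structure.
#' @param Dp prescribed dose (Gy), > 0.
#' @param alpha cell-sensitivity parameter, > 0.
#' @return `ltcp()`: dimensionless positive penalty; 1 when the dose is
#'   uniform at `Dp`, below 1 when the target is (over)dosed, growing
#'   exponentially with underdose.
#' @examples
#' ltcp(c(44, 45, 46), Dp = 45, alpha = 4)
#' geud(c(10, 20), k = 6)
#' volume_at_dose(c(5, 15, 25, 35), 12)
#' @export
ltcp <- function(d, Dp, alpha) {
  check_dose_vector(d)
  stopifnot(Dp > 0, alpha > 0)
  exp(log_ltcp(d, Dp, alpha))
}

# log LTCP via log-sum-exp; stable for doses far below Dp
log_ltcp <- function(d, Dp, alpha) {
  e <- -alpha * (d - Dp)
  m <- max(e)
  m + log(mean(exp(e - m)))
}

#' @rdname ltcp
#' @param k volume-effect parameter (power of the mean), >= 1. `k = 1` gives
#'   the arithmetic mean; large `k` approaches the maximum dose.
#' @export
geud <- function(d, k) {
  check_dose_vector(d)
  if (k < 1) stop("'k' must be >= 1 (the wish-list uses the convex regime)")
  mx <- max(d)
  if (mx == 0) return(0)
  # factor out the max so d^k cannot overflow for large k
  mx * mean((d / mx)^k)^(1 / k)
}

#' @rdname ltcp
#' @export
mean_dose <- function(d) {
  check_dose_vector(d)
  mean(d)
}

#' @rdname ltcp
#' @export
max_dose <- function(d) {
  check_dose_vector(d)
  max(d)
}

#' @rdname ltcp
#' @param threshold dose threshold (Gy).
#' @return `volume_at_dose()`: percent of voxels with dose `>= threshold`.
#' @export
volume_at_dose <- function(d, threshold) {
  check_dose_vector(d)
  100 * mean(d >= threshold)
}

check_dose_vector <- function(d) {
  if (!is.numeric(d) || length(d) == 0)
    stop("dose vector must be non-empty numeric")
  if (any(!is.finite(d)) || any(d < -1e-9))
    stop("dose vector must be finite and nonnegative")
  invisible(TRUE)
}

# evaluate a wish-list objective row (resolved to Gy) on a dose vector;
# single code path shared by the optimizer ledger and verify_plan
eval_objective <- function(obj, d) {
  switch(obj$kind,
    "LTCP" = ltcp(d, Dp = obj$params$Dp, alpha = obj$params$alpha),
    "mean" = mean_dose(d),
    "EUD" = geud(d, k = obj$params$k),
    "maximum" = max_dose(d),
    "dose-volume" = volume_at_dose(d, obj$params$threshold),
    stop("unknown objective kind: ", obj$kind))
}
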