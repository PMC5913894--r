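#' Cumulative dose-volume histogram
#'
#' `V(t)` is the fraction of the structure's voxels receiving at least `t` Gy.
#' With `n_bins = NULL` (default) the curve is exact: a step function with a
#' vertical segment at every distinct dose value (represented by duplicated
#' dose entries). With `n_bins` set, `V` is sampled on a regular dose grid
#' from 0 to just past the maximum dose.
#'
#' @param d nonnegative voxel doses (Gy) of one structure (non-empty).
#' @param n_bins number of regular dose bins, >= 2, or `NULL` for the exact
#'   step curve.
#' @param volume_cc optional physical volume represented by the curve.
#' @return An object of class `dvh_curve` with fields `dose` (Gy, ascending,
#'   possibly duplicated at steps) and `volume` (fraction in `[0, 1]`,
#'   nonincreasing, starting at 1).
#' @examples
#' dvh <- compute_dvh(c(0, 10, 20, 30))
#' dose_at_volume(dvh, 50)
#' @export
compute_dvh <- function(d, n_bins = NULL, volume_cc = NA_real_) {
  check_dose_vector(d)
  n <- length(d)
  if (is.null(n_bins)) {
    u <- sort(unique(d))
    v_at <- vapply(u, function(t) sum(d >= t) / n, 0)
    v_after <- c(v_at[-1], 0)
    dose <- rep(u, each = 2)
    vol <- as.numeric(rbind(v_at, v_after))
    if (u[1] > 0) { dose <- c(0, dose); vol <- c(1, vol) }
  } else {
    n_bins <- as.integer(n_bins)
    if (n_bins < 2) stop("'n_bins' must be >= 2")
    mx <- max(d)
    if (mx == 0) mx <- 1
    bw <- mx / (n_bins - 1L)
    dose <- c(seq(0, mx, length.out = n_bins), mx + bw)
    vol <- vapply(dose, function(t) sum(d >= t) / n, 0)
  }
  dvh_curve(dose, vol, volume_cc)
}

#' @rdname compute_dvh
#' @param dose ascending dose grid (Gy); duplicated values encode steps.
#' @param volume nonincreasing cumulative volume fraction starting at 1.
#' @export
dvh_curve <- function(dose, volume, volume_cc = NA_real_) {
  if (length(dose) == 0 || length(dose) != length(volume))
    stop("'dose' and 'volume' must be non-empty and of equal length")
  if (is.unsorted(dose)) stop("DVH dose grid must be ascending")
  if (any(volume < -1e-12) || any(volume > 1 + 1e-12))
    stop("DVH volume fractions must lie in [0, 1]")
  if (any(diff(volume) > 1e-12))
    stop("DVH volume fractions must be nonincreasing")
  if (abs(volume[1] - 1) > 1e-12)
    stop("DVH must start at volume fraction 1")
  structure(list(dose = as.numeric(dose), volume = pmin(pmax(volume, 0), 1),
                 volume_cc = volume_cc),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d points, dose 0..%.2f Gy, mean %.2f Gy\n",
              length(x$dose), max(x$dose), dvh_mean_dose(x)))
  invisible(x)
}

#' Build a synthetic cumulative DVH from level/fraction pairs
#'
#' Interprets `(dose_levels[j], volume_fractions[j])` as a step curve: the
#' cumulative fraction drops from `volume_fractions[j]` to
#' `volume_fractions[j+1]` at `dose_levels[j]`, and to 0 at the last level.
#' Useful as a fixture for NTCP calculations independent of any optimization.
#'
#' @param organ_volume_cc physical organ volume (cc).
#' @param dose_levels ascending dose levels (Gy), non-empty.
#' @param volume_fractions cumulative fractions at the levels: nonincreasing,
#'   starting at 1, within `[0, 1]`.
#' @return A [dvh_curve()].
#' @examples
#' make_synthetic_dvh(150, c(0, 30), c(1, 0.5))  # half the organ at 30 Gy
#' @export
make_synthetic_dvh <- function(organ_volume_cc, dose_levels,
                               volume_fractions) {
  if (length(dose_levels) == 0) stop("'dose_levels' must be non-empty")
  if (length(dose_levels) != length(volume_fractions))
    stop("'dose_levels' and 'volume_fractions' lengths differ")
  if (is.unsorted(dose_levels, strictly = TRUE))
    stop("'dose_levels' must be strictly ascending")
  if (any(dose_levels < 0)) stop("'dose_levels' must be nonnegative")
  f <- volume_fractions
  if (abs(f[1] - 1) > 1e-12) stop("'volume_fractions' must start at 1.0")
  if (any(f < 0 | f > 1)) stop("'volume_fractions' must lie in [0, 1]")
  if (any(diff(f) > 1e-12)) stop("'volume_fractions' must be nonincreasing")
  m <- length(f)
  nxt <- c(f[-1], 0)
  dose <- rep(dose_levels, each = 2)
  vol <- as.numeric(rbind(f, nxt))
  if (dose_levels[1] > 0) { dose <- c(0, dose); vol <- c(1, vol) }
  dvh_curve(dose, vol, organ_volume_cc)
}

#' Dose covering the hottest q% of a structure (D_q%)
#'
#' Inverts the cumulative DVH at level `q/100`: finds the last curve point
#' with `V >= q/100` and linearly interpolates to the next point. On exact
#' step curves vertical segments make step doses exact (a uniform 10 Gy
#' structure gives `D_50% = 10`); on binned curves the result agrees with the
#' direct order statistic within one bin width.
#'
#' @param dvh a [dvh_curve()].
#' @param q volume percent in (0, 100).
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, q) {
  stopifnot(inherits(dvh, "dvh_curve"), q > 0, q < 100)
  qq <- q / 100
  v <- dvh$volume; t <- dvh$dose
  i <- max(which(v >= qq - 1e-15))
  if (i == length(v)) return(t[i])
  if (v[i] - v[i + 1] < 1e-15) return(t[i])
  t[i] + (v[i] - qq) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
}

#' Mean dose implied by a DVH curve
#'
#' Integrates the differential DVH: each drop of the cumulative curve between
#' adjacent points contributes its mass at the segment's dose midpoint; any
#' residual fraction at the end of the curve is counted at the final dose.
#'
#' @param dvh a [dvh_curve()].
#' @return mean dose in Gy.
#' @export
dvh_mean_dose <- function(dvh) {
  dd <- dvh_differential(dvh)
  sum(dd$dose * dd$mass)
}

# differential DVH: (dose, mass) pairs with total mass 1
dvh_differential <- function(dvh) {
  stopifnot(inherits(dvh, "dvh_curve"))
  v <- dvh$volume; t <- dvh$dose
  n <- length(v)
  drop <- v[-n] - v[-1]
  mid <- (t[-n] + t[-1]) / 2
  keep <- drop > 0
  dose <- mid[keep]; mass <- drop[keep]
  if (v[n] > 0) { dose <- c(dose, t[n]); mass <- c(mass, v[n]) }
  list(dose = dose, mass = mass)
}

#' Rescale a plan so the PTV median dose equals the prescription
#'
#' Fluence and dose are linear in each other, so both are multiplied by
#' `target_median / D_50%(PTV)`. After the call the PTV `D_50%` equals
#' `target_median` to machine precision; every other dose metric scales by
#' the same factor.
#'
#' @param p a plan from [solve_prioritized()] or [solve_baseline()].
#' @param s the [structure_set()] the plan was computed on.
#' @param target_median target PTV median dose (Gy), default the plan's
#'   prescription (45 Gy for the gastric wish-list).
#' @return The rescaled plan; `p$normalization` records the factor.
#' @export
normalize_plan <- function(p, s, target_median = NULL) {
  stopifnot(inherits(p, "rt_plan"), inherits(s, "structure_set"))
  if (is.null(target_median)) target_median <- p$prescription_gy
  stopifnot(is.numeric(target_median), target_median > 0)
  d_ptv <- structure_dose(p, s, "PTV")
  cur <- dose_at_volume(compute_dvh(d_ptv), 50)
  if (cur <= 0) stop("PTV median dose is zero; cannot normalize")
  f <- target_median / cur
  p$fluence <- p$fluence * f
  p$dose <- p$dose * f
  p$normalization <- list(factor = f, target_median_gy = target_median)
  p
}

#' Homogeneity index
#'
#' `HI = (D_2% - D_98%) / D_50%`: 0 for a perfectly uniform target dose.
#'
#' @param D2,D98,D50 near-maximum, near-minimum and median target dose (Gy).
#' @export
homogeneity_index <- function(D2, D98, D50) {
  stopifnot(D50 > 0)
  (D2 - D98) / D50
}

#' Conformity index
#'
#' `CI = TV_RI^2 / (TV * V_RI)` where `TV` is the target volume, `V_RI` the
#' volume of the reference isodose, and `TV_RI` their intersection; 1 for
#' perfect conformity.
#'
#' @param TV target volume (cc), > 0.
#' @param TV_RI target volume covered by the reference isodose (cc).
#' @param V_RI reference isodose volume (cc), > 0.
#' @export
conformity_index <- function(TV, TV_RI, V_RI) {
  if (!(TV > 0 && V_RI > 0)) stop("TV and V_RI must be positive")
  if (TV_RI > min(TV, V_RI) + 1e-9)
    stop("TV_RI cannot exceed min(TV, V_RI)")
  TV_RI^2 / (TV * V_RI)
}

#' Integral-dose summary of a plan
#'
#' Whole-body dose burden: mean Body dose plus the percent of Body receiving
#' at least each threshold (defaults 5, 11.25 and 22.5 Gy, i.e. roughly 11%,
#' 25% and 50% of a 45 Gy prescription).
#'
#' @param p a plan.
#' @param s the structure set.
#' @param thresholds_gy dose thresholds (Gy).
#' @return data.frame with columns `metric`, `value`.
#' @export
integral_dose_summary <- function(p, s, thresholds_gy = c(5, 11.25, 22.5)) {
  d <- structure_dose(p, s, "Body")
  out <- data.frame(metric = c("D_mean_Gy",
                               sprintf("V_%gGy_pct", thresholds_gy)),
                    value = c(mean_dose(d),
                              vapply(thresholds_gy,
                                     function(t) volume_at_dose(d, t), 0)))
  out
}

#' Dose received by one structure under a plan
#'
#' @param p a plan.
#' @param s the structure set.
#' @param name structure name.
#' @return numeric vector of voxel doses (Gy).
#' @export
structure_dose <- function(p, s, name) {
  stopifnot(inherits(p, "rt_plan"))
  m <- s$masks[[name]]
  if (is.null(m)) stop("no structure named '", name, "'")
  rows <- match(which(m), p$body_idx)
  if (anyNA(rows)) stop("structure '", name, "' has voxels outside Body")
  p$dose[rows]
}

#' Table-2-style plan metrics
#'
#' Computes the full per-structure metric set used for plan comparison:
#' PTV `V_95%`, `D_98%`, `D_2%`, HI and CI; kidney, liver-PTV `D_mean`,
#' `D_30%`, `D_50%`, `D_60%` and dose-volume percentages; heart and spinal
#' cord mean/maximum dose; lung mean dose and `V_5Gy`/`V_20Gy`; Body
#' integral-dose summary. The CI reference isodose defaults to 95% of the
#' prescription.
#'
#' @param p a (normalized) plan.
#' @param s a structure set with derived structures
#'   (see [expand_structures()]).
#' @param ci_reference_fraction reference isodose as a fraction of the
#'   prescription used for CI and PTV coverage, default 0.95.
#' @return data.frame with columns `structure`, `metric`, `value`, `units`.
#' @export
plan_metrics <- function(p, s, ci_reference_fraction = 0.95) {
  Dp <- p$prescription_gy
  ri <- ci_reference_fraction * Dp
  vox_cc <- s$grid$voxel_volume_cc
  rows <- list()
  add <- function(structure, metric, value, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, metric = metric, value = value, units = units,
      stringsAsFactors = FALSE)

  d_ptv <- structure_dose(p, s, "PTV")
  dvh_ptv <- compute_dvh(d_ptv)
  D2 <- dose_at_volume(dvh_ptv, 2); D98 <- dose_at_volume(dvh_ptv, 98)
  D50 <- dose_at_volume(dvh_ptv, 50)
  add("PTV", "V_95pct_pct", volume_at_dose(d_ptv, ri), "%")
  add("PTV", "D_98pct_Gy", D98, "Gy")
  add("PTV", "D_2pct_Gy", D2, "Gy")
  add("PTV", "HI", homogeneity_index(D2, D98, D50), "")
  d_body <- structure_dose(p, s, "Body")
  TV <- length(d_ptv) * vox_cc
  V_RI <- sum(d_body >= ri) * vox_cc
  TV_RI <- sum(d_ptv >= ri) * vox_cc
  add("PTV", "CI", if (V_RI > 0) conformity_index(TV, TV_RI, V_RI)
                   else NA_real_, "")

  oar_dq <- function(nm, vd_gy) {
    if (is.null(s$masks[[nm]])) return(invisible(NULL))
    d <- structure_dose(p, s, nm)
    dvh <- compute_dvh(d)
    add(nm, "D_mean_Gy", mean_dose(d), "Gy")
    for (q in c(30, 50, 60))
      add(nm, sprintf("D_%dpct_Gy", q), dose_at_volume(dvh, q), "Gy")
    for (t in vd_gy)
      add(nm, sprintf("V_%gGy_pct", t), volume_at_dose(d, t), "%")
  }
  oar_dq("KidneyL", c(12, 20))
  oar_dq("KidneyR", c(12, 20))
  oar_dq("Liver-PTV", c(24, 30))
  for (nm in c("Heart", "SpinalCord")) {
    d <- structure_dose(p, s, nm)
    add(nm, "D_mean_Gy", mean_dose(d), "Gy")
    add(nm, "D_max_Gy", max_dose(d), "Gy")
  }
  for (nm in c("LungL", "LungR")) {
    d <- structure_dose(p, s, nm)
    add(nm, "D_mean_Gy", mean_dose(d), "Gy")
    add(nm, "V_5Gy_pct", volume_at_dose(d, 5), "%")
    add(nm, "V_20Gy_pct", volume_at_dose(d, 20), "%")
  }
  ids <- integral_dose_summary(p, s)
  for (i in seq_len(nrow(ids)))
    add("Body", ids$metric[i], ids$value[i],
        if (grepl("pct", ids$metric[i])) "%" else "Gy")
  do.call(rbind, rows)
}
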