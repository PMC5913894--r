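#' Configuration for a paired planning study
#'
#' Describes a synthetic cohort: each subject is a seeded phantom on which a
#' prioritized plan and a weighted-sum baseline plan are generated, both
#' normalized to the prescribed median PTV dose, evaluated and compared.
#' Subject-to-subject variability comes from the phantom generator's seeded
#' jitter of organ positions and sizes.
#'
#' @param seed study master seed; subject i uses `seed * 1000 + i` for its
#'   phantom (kept below 2^31).
#' @param n_subjects number of synthetic subjects, >= 1.
#' @param grid the [voxel_grid()] for all subjects.
#' @param difficulty phantom difficulty, see [make_phantom()].
#' @param wishlist_path wish-list YAML; default the packaged gastric
#'   wish-list.
#' @param baseline_weights weighted-sum template weights (one per wish-list
#'   objective row); the default emphasizes target coverage and conformity
#'   and under-weights the kidneys, emulating a generic template not tuned to
#'   kidney sparing.
#' @param n_beams,beamlet_size_mm influence-matrix settings
#'   (see [make_influence()]).
#' @param options solver options ([plan_options()]).
#' @param out_dir output directory, or `NULL` for no file output.
#' @param verbose print progress.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 3L,
                       grid = voxel_grid(c(32, 32, 16), spacing = 6),
                       difficulty = "clinical-like",
                       wishlist_path = NULL,
                       baseline_weights = NULL,
                       n_beams = 9, beamlet_size_mm = 12,
                       options = plan_options(),
                       out_dir = NULL, verbose = FALSE) {
  stopifnot(n_subjects >= 1, abs(seed) < 2^21)
  if (is.null(wishlist_path))
    wishlist_path <- system.file("extdata", "gastric_wishlist.yaml",
                                 package = "wishplan", mustWork = TRUE)
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              grid = grid, difficulty = difficulty,
              wishlist_path = wishlist_path,
              baseline_weights = baseline_weights,
              n_beams = n_beams, beamlet_size_mm = beamlet_size_mm,
              options = options, out_dir = out_dir, verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

# default template: strong coverage/conformity weights, kidneys neglected
default_baseline_weights <- function(w) {
  vapply(w$objectives, function(ob) {
    if (ob$kind == "LTCP") 30
    else if (ob$volume == "Kidneys") 0.02
    else if (ob$kind == "maximum") 2
    else 0.5
  }, 0)
}

#' Run a paired synthetic planning study
#'
#' For each subject: generate the seeded phantom and its derived shells,
#' build the influence matrix, solve the prioritized plan and the
#' template-weighted baseline, normalize both to the prescribed median PTV
#' dose, compute the Table-2-style metric set and organ NTCPs, and finally
#' assemble the paired Wilcoxon comparison report across subjects. A failed
#' subject is logged and skipped; the study continues.
#'
#' @param cfg a [run_config()].
#' @return list of class `study_result`: `subjects` (per-subject plans and
#'   metric tables), `pairs` (long data.frame of paired metric values),
#'   `report` ([summarize_pairs()] output), `manifest` (seeds, config hash,
#'   package version, skips). If `cfg$out_dir` is set, CSV tables and a JSON
#'   manifest are written there.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  w <- resolve_limits(load_wishlist(cfg$wishlist_path))
  bw <- cfg$baseline_weights %||% default_baseline_weights(w)
  subjects <- list()
  skipped <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sseed <- cfg$seed * 1000L + i
    if (cfg$verbose) message("subject ", i, " (seed ", sseed, ")")
    res <- tryCatch({
      s <- make_phantom(sseed, cfg$grid, cfg$difficulty)
      s <- expand_structures(s)
      A <- make_influence(s, n_beams = cfg$n_beams,
                          beamlet_size_mm = cfg$beamlet_size_mm,
                          seed = sseed)
      pp <- solve_prioritized(w, A, s, cfg$options)
      pb <- solve_baseline(bw, w, A, s, cfg$options)
      verify_pp <- verify_plan(pp, w, A, s)
      pp <- normalize_plan(pp, s)
      pb <- normalize_plan(pb, s)
      mp <- plan_metrics(pp, s)
      mb <- plan_metrics(pb, s)
      np <- organ_ntcp_report(pp, s)
      nb <- organ_ntcp_report(pb, s)
      list(seed = sseed, structures = s,
           verify_prioritized = verify_pp,
           prioritized = pp, baseline = pb,
           metrics_prioritized = mp, metrics_baseline = mb,
           ntcp_prioritized = np, ntcp_baseline = nb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", i, " skipped: ", conditionMessage(res))
      skipped[[length(skipped) + 1L]] <- list(subject = i, seed = sseed,
                                              reason = conditionMessage(res))
    } else subjects[[length(subjects) + 1L]] <- res
  }
  if (!length(subjects)) stop("no subject completed")

  pairs <- do.call(rbind, lapply(subjects, function(sub) {
    key <- paste(sub$metrics_prioritized$structure,
                 sub$metrics_prioritized$metric)
    stopifnot(identical(key, paste(sub$metrics_baseline$structure,
                                   sub$metrics_baseline$metric)))
    m <- data.frame(subject_seed = sub$seed, metric = key,
                    baseline = sub$metrics_baseline$value,
                    prioritized = sub$metrics_prioritized$value,
                    stringsAsFactors = FALSE)
    n <- data.frame(subject_seed = sub$seed,
                    metric = paste(sub$ntcp_prioritized$structure,
                                   "NTCP_pct"),
                    baseline = sub$ntcp_baseline$ntcp_pct,
                    prioritized = sub$ntcp_prioritized$ntcp_pct,
                    stringsAsFactors = FALSE)
    rbind(m, n)
  }))
  report <- summarize_pairs(pairs)

  cfg_str <- jsonlite::toJSON(list(
    seed = cfg$seed, n_subjects = cfg$n_subjects,
    grid = list(shape = cfg$grid$shape, spacing = cfg$grid$spacing),
    difficulty = cfg$difficulty, n_beams = cfg$n_beams,
    beamlet_size_mm = cfg$beamlet_size_mm, baseline_weights = bw),
    auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_str), tf)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("wishplan")),
                   seed = cfg$seed,
                   subject_seeds = vapply(subjects, `[[`, 0, "seed"),
                   config_hash = unname(tools::md5sum(tf)),
                   config = jsonlite::fromJSON(cfg_str),
                   skipped = skipped)
  unlink(tf)

  out <- structure(list(subjects = subjects, pairs = pairs, report = report,
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pairs, file.path(cfg$out_dir, "paired_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(cfg$out_dir, "comparison_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (sub in subjects) {
      sd <- file.path(cfg$out_dir, sprintf("subject_%d", sub$seed))
      write_plan(sub$prioritized, file.path(sd, "prioritized"))
      write_plan(sub$baseline, file.path(sd, "baseline"))
    }
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects, %d paired metrics\n",
              length(x$subjects), length(unique(x$pairs$metric))))
  format_pair_report(x$report)
  invisible(x)
}
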