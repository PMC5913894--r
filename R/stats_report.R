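#' Paired two-sided Wilcoxon signed-rank test
#'
#' Wraps the signed-rank test with the conventions used for plan comparison:
#' two-sided, paired differences `x - y`. Zero differences are dropped by
#' default (the classic Wilcoxon convention); the Pratt variant, which ranks
#' zeros before discarding them, is available via `zeros = "pratt"`. In
#' `"exact"` mode the exact null distribution is used when there are no ties
#' among the absolute differences and `n <= 25`; otherwise (and in
#' `"normal-approx"` mode) a tie- and continuity-corrected normal
#' approximation is used.
#'
#' @param x,y paired samples (e.g. baseline and prioritized plan metric), or
#'   `y = NULL` with `x` the vector of differences.
#' @param mode `"exact"` or `"normal-approx"`.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n_used` (pairs after zero handling), and `method`.
#' @examples
#' wilcoxon_signed_rank(c(3, 5, 2, 6, 4), rep(0, 5))$p_value  # 2/32
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("exact", "normal-approx"),
                                 zeros = c("drop", "pratt")) {
  mode <- match.arg(mode)
  zeros <- match.arg(zeros)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (!length(d) || any(!is.finite(d))) stop("differences must be finite")
  if (all(d == 0)) {
    warning("all paired differences are zero; p-value set to 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate"))
  }
  if (zeros == "drop") {
    dnz <- d[d != 0]
    r <- rank(abs(dnz))
    V <- sum(r[dnz > 0])
    n <- length(dnz)
    ties <- anyDuplicated(abs(dnz)) > 0
    if (mode == "exact" && !ties && n <= 25) {
      # exact two-sided p from the signed-rank null (sum over 2^n sign
      # patterns, computed by stats::psignrank)
      p_lo <- stats::psignrank(V, n)
      p_hi <- stats::psignrank(V - 1, n, lower.tail = FALSE)
      p <- min(1, 2 * min(p_lo, p_hi))
      return(list(statistic = V, p_value = p, n_used = n,
                  method = "exact signed-rank"))
    }
    # tie- and continuity-corrected normal approximation
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    return(list(statistic = V, p_value = p, n_used = n,
                method = "normal approximation"))
  }
  # Pratt: rank |d| including zeros, drop the zero ranks from the statistic
  r <- rank(abs(d))
  nz <- d != 0
  V <- sum(r[d > 0])
  n <- length(d)
  r0 <- r[!nz]
  mu <- (n * (n + 1) / 4) - sum(r0) / 2
  tie_tab <- table(r[nz])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(r0^2) / 4 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu) / sqrt(max(sig2, .Machine$double.eps))
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, p_value = p, n_used = sum(nz),
       method = "Pratt normal approximation")
}

#' Summarize paired plan-metric samples, Table-2 style
#'
#' For each metric: the prioritized-plan population mean and SD, the mean and
#' SD of the paired difference `baseline - prioritized` (positive values
#' favour the prioritized plans), the two-sided Wilcoxon signed-rank p-value,
#' and a significance flag. SDs use the `n - 1` denominator.
#'
#' @param pairs a data.frame with columns `metric`, `baseline`,
#'   `prioritized` (one row per subject and metric), and optionally `units`
#'   and `structure`.
#' @param alpha significance level, default 0.05.
#' @param mode passed to [wilcoxon_signed_rank()].
#' @return data.frame with one row per metric: `metric`, `n`,
#'   `prioritized_mean`, `prioritized_sd`, `diff_mean`, `diff_sd`,
#'   `p_value`, `significant`.
#' @export
summarize_pairs <- function(pairs, alpha = 0.05,
                            mode = c("exact", "normal-approx")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pairs),
            all(c("metric", "baseline", "prioritized") %in% names(pairs)))
  keys <- unique(pairs$metric)
  out <- lapply(keys, function(k) {
    sub <- pairs[pairs$metric == k, , drop = FALSE]
    b <- sub$baseline; a <- sub$prioritized
    dd <- b - a
    p <- if (all(dd == 0)) 1
         else suppressWarnings(wilcoxon_signed_rank(b, a, mode = mode)$p_value)
    data.frame(metric = k, n = length(a),
               prioritized_mean = mean(a),
               prioritized_sd = if (length(a) > 1) sd(a) else NA_real_,
               diff_mean = mean(dd),
               diff_sd = if (length(dd) > 1) sd(dd) else NA_real_,
               p_value = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a paired summary as plain text
#'
#' @param summary a [summarize_pairs()] result.
#' @return character vector of lines, invisibly; also printed.
#' @export
format_pair_report <- function(summary) {
  lines <- c(sprintf("%-28s %7s %18s %18s %9s", "Metric", "n",
                     "Prioritized (mean+-SD)", "Diff (mean+-SD)", "p"),
             strrep("-", 86))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf(
      "%-28s %7d %9.3f +- %-6.3f %9.3f +- %-6.3f %9.4g%s",
      r$metric, r$n, r$prioritized_mean,
      ifelse(is.na(r$prioritized_sd), 0, r$prioritized_sd),
      r$diff_mean, ifelse(is.na(r$diff_sd), 0, r$diff_sd),
      r$p_value, ifelse(isTRUE(r$significant), " *", "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
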