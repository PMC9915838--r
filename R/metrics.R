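# Strategy comparison statistics ------------------------------------------

#' Rate per number of variants assessed
#'
#' The efficiency metric of the comparison: hits (diagnoses, or reportable
#' variants) divided by the number of variants a laboratory must assess,
#' expressed as a percentage. Scale-invariant in its two arguments.
#'
#' @param n_hits Number of diagnostic (or reportable) variants.
#' @param n_assessed Number of variants assessed; must be positive.
#' @return Percentage (numeric scalar), unrounded.
#' @export
rate_per_assessed <- function(n_hits, n_assessed) {
  if (any(n_assessed <= 0)) stop("n_assessed must be positive")
  if (any(n_hits < 0 | n_hits > n_assessed))
    stop("n_hits must lie in [0, n_assessed]")
  100 * n_hits / n_assessed
}

#' Paired Wilcoxon signed-rank test
#'
#' Two methods:
#' * `normal_cc` (default) — normal approximation with continuity
#'   correction and the tie variance correction, as implemented by
#'   [stats::wilcox.test()] with `exact = FALSE, correct = TRUE`;
#' * `exact` — full enumeration of all `2^n` sign assignments over the
#'   ranks of the absolute differences, using mid-ranks for ties; the
#'   two-sided p-value doubles the smaller tail (capped at 1).
#'
#' Zero differences are dropped under both methods. If every difference is
#' zero the p-value is 1 with a warning. Fewer than 3 non-zero differences
#' triggers a warning (the test is degenerate at that size).
#'
#' @param x,y Paired observations; or supply differences via `x` with
#'   `y = NULL`.
#' @param method `"normal_cc"` or `"exact"`.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `method` and `n_used` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 method = c("normal_cc", "exact")) {
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop("missing values in paired differences")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, method = method, n_used = 0L))
  }
  if (n < 3) warning("fewer than 3 non-zero differences")
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (method == "normal_cc") {
    wt <- suppressWarnings(stats::wilcox.test(nz, exact = FALSE,
                                              correct = TRUE))
    p <- wt$p.value
  } else {
    if (n > 20) stop("exact enumeration limited to 20 non-zero differences")
    # distribution of V over all sign assignments of the ranks
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% r
    lower <- mean(vs <= v)
    upper <- mean(vs >= v)
    p <- min(1, 2 * min(lower, upper))
  }
  list(statistic = as.numeric(v), p_value = p, method = method,
       n_used = as.integer(n))
}

#' Compare the two triage strategies across a cohort
#'
#' Takes per-family assessed counts for both strategies plus the two
#' reported-variant tables, and computes the cohort comparison: summed
#' assessed/diagnostic/reportable counts restricted to the families
#' comparable across both arms, the six efficiency rates, the overlap of
#' the reported sets (by `chrom:pos:ref:alt` identity), and paired
#' Wilcoxon signed-rank tests on the per-family assessed counts.
#' Copy-number variants are outside these counts by construction.
#'
#' Families lacking a result in either arm, or flagged not `paired`
#' (e.g. a family whose sequenced structure differed between arms), are
#' dropped from the paired analysis with a warning; the family sets
#' entering both arms of each paired test are asserted identical.
#'
#' @param family_counts Data frame with columns `family`,
#'   `hippo_variants`, `hippo_gencc_variants`, `gms_passing` (NA when no
#'   result) and optionally `paired` (logical).
#' @param hippo_reported Data frame of variants reported by the
#'   panel-agnostic arm: columns `family`, `variant` (key), `diagnostic`
#'   (logical).
#' @param gms_reported Same layout for the panel-based arm.
#' @return List of class `comparison_result`.
#' @export
compare_strategies <- function(family_counts, hippo_reported, gms_reported) {
  fc <- family_counts
  if (is.null(fc$paired)) fc$paired <- TRUE
  usable <- fc$paired & !is.na(fc$gms_passing) & !is.na(fc$hippo_variants)
  dropped <- fc$family[!usable]
  if (length(dropped))
    warning("families dropped from paired analysis: ",
            paste(dropped, collapse = ", "))
  pairs <- fc[usable, , drop = FALSE]
  stopifnot(nrow(pairs) > 0)

  in_pairs <- function(df) df[df$family %in% pairs$family, , drop = FALSE]
  hippo_paired <- in_pairs(hippo_reported)
  gms_paired <- in_pairs(gms_reported)

  n <- list(
    hippo_assessed = sum(pairs$hippo_variants),
    hippo_gencc_assessed = sum(pairs$hippo_gencc_variants),
    gms_assessed = sum(pairs$gms_passing),
    hippo_diagnostic = sum(hippo_paired$diagnostic),
    gms_diagnostic = sum(gms_paired$diagnostic),
    hippo_reportable = nrow(hippo_paired),
    gms_reportable = nrow(gms_paired)
  )
  rates <- list(
    hippo_diagnostic = rate_per_assessed(n$hippo_diagnostic, n$hippo_assessed),
    hippo_gencc_diagnostic = rate_per_assessed(n$hippo_diagnostic,
                                               n$hippo_gencc_assessed),
    gms_diagnostic = rate_per_assessed(n$gms_diagnostic, n$gms_assessed),
    hippo_reportable = rate_per_assessed(n$hippo_reportable,
                                         n$hippo_assessed),
    hippo_gencc_reportable = rate_per_assessed(n$hippo_reportable,
                                               n$hippo_gencc_assessed),
    gms_reportable = rate_per_assessed(n$gms_reportable, n$gms_assessed)
  )
  overlap <- length(intersect(unique(hippo_reported$variant),
                              unique(gms_reported$variant)))

  wilcox_all <- wilcoxon_signed_rank(pairs$hippo_variants,
                                     pairs$gms_passing)
  wilcox_gencc <- wilcoxon_signed_rank(pairs$hippo_gencc_variants,
                                       pairs$gms_passing)

  structure(list(families = pairs$family, dropped_families = dropped,
                 per_family = pairs, counts = n, rates = rates,
                 overlap = overlap,
                 wilcoxon = list(all_genes_vs_gms = wilcox_all,
                                 gencc_vs_gms = wilcox_gencc)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result over", length(x$families), "paired families>\n")
  cat(sprintf("  assessed:   panel-agnostic %d (GenCC-restricted %d) vs panel-based %d\n",
              x$counts$hippo_assessed, x$counts$hippo_gencc_assessed,
              x$counts$gms_assessed))
  cat(sprintf("  diagnostic: %d vs %d; reportable: %d vs %d; overlap %d\n",
              x$counts$hippo_diagnostic, x$counts$gms_diagnostic,
              x$counts$hippo_reportable, x$counts$gms_reportable,
              x$overlap))
  cat(sprintf("  diagnostic rate/variant assessed: %.2f%% (all genes), %.2f%% (GenCC), %.2f%% (panel-based)\n",
              x$rates$hippo_diagnostic, x$rates$hippo_gencc_diagnostic,
              x$rates$gms_diagnostic))
  cat(sprintf("  Wilcoxon signed-rank p: %.3g (all genes), %.3g (GenCC)\n",
              x$wilcoxon$all_genes_vs_gms$p_value,
              x$wilcoxon$gencc_vs_gms$p_value))
  invisible(x)
}
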