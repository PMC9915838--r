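# Filter configuration ---------------------------------------------------

.hippo_defaults <- function() {
  list(
    strategy = "hippo",
    af_max_dominant = 0.001,
    af_max_recessive = 0.05,
    cohort_af_max = 0.01,
    coding_window_bp = 20,
    spliceai_min = 0.2,
    cadd_min = 15,
    allele_balance_min = 0.2,
    gq_min = 40,
    require_pass = FALSE,
    # Safety ceiling for the ClinVar pathogenic override: a P/LP assertion
    # rescues a variant from every other rule, but not above this
    # population frequency.
    override_af_ceiling = 0.05,
    gq_all_members = FALSE,
    min_parent_depth = 0,
    lof_terms = lof_terms()
  )
}

.gms_defaults <- function() {
  list(
    strategy = "gms",
    af_max_dominant = 0.001,
    af_max_recessive = 0.01,
    cohort_af_max = NA_real_,
    coding_window_bp = 8,
    spliceai_min = NA_real_,
    cadd_min = NA_real_,
    allele_balance_min = NA_real_,
    gq_min = 30,
    require_pass = TRUE,
    exomiser_score_min = 0.95,
    exomiser_rank_max = 3,
    cnv_min_size_bp = 10000,
    lof_terms = lof_terms()
  )
}

#' Filtering thresholds for a triage strategy
#'
#' Builds the threshold set driving either retention strategy. Defaults are
#' the published criteria of each workflow: the panel-agnostic ("hippo")
#' strategy uses allele frequency < 0.001 (dominant) / < 0.05 (recessive),
#' cohort AF < 0.01, coding +/- 20 bp, SpliceAI > 0.2 for splicing variants,
#' CADD > 15, allele balance > 0.2 and genotype quality > 40 with no
#' FILTER-status requirement; the panel-based ("gms") strategy uses allele
#' frequency < 0.001 / < 0.01, coding +/- 8 bp, genotype quality > 30,
#' PASS-only calls, an Exomiser gene-agnostic channel (rank <= 3, score
#' >= 0.95) and a 10 kb minimum CNV size. All comparisons against these
#' thresholds are strict inequalities as printed (e.g. allele balance
#' exactly 0.2 fails).
#'
#' @param strategy `"hippo"` or `"gms"`.
#' @param ... Named threshold overrides; unknown names are an error. Any
#'   override is recorded in the `overrides` attribute.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(strategy = c("hippo", "gms"), ...) {
  strategy <- match.arg(strategy)
  cfg <- if (strategy == "hippo") .hippo_defaults() else .gms_defaults()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown filter_config fields: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(all(vapply(cfg[!names(cfg) %in% c("strategy", "lof_terms",
                                              "require_pass",
                                              "gq_all_members")],
                       function(x) is.na(x) || is.finite(x), logical(1))))
  structure(cfg, class = c("filter_config", "list"),
            overrides = names(dots))
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config: ", x$strategy, " strategy>\n", sep = "")
  ov <- attr(x, "overrides")
  for (nm in setdiff(names(x), "strategy")) {
    val <- x[[nm]]
    cat(sprintf("  %-20s %s%s\n", nm, paste(val, collapse = ","),
                if (nm %in% ov) "  [override]" else ""))
  }
  invisible(x)
}

#' Read a filter configuration from YAML
#'
#' The YAML file names a `strategy` and optionally overrides individual
#' thresholds; unspecified values keep the strategy defaults.
#'
#' @param path Path to a YAML file.
#' @return A [filter_config()] object.
#' @export
read_filter_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$strategy))
    stop("config YAML must declare a 'strategy' (hippo or gms): ", path)
  strategy <- y$strategy
  y$strategy <- NULL
  do.call(filter_config, c(list(strategy = strategy), y))
}

# Threshold selection by inheritance search mode.
af_max_for_mode <- function(cfg, mode) {
  if (identical(mode, "recessive")) cfg$af_max_recessive else cfg$af_max_dominant
}

# Search mode implied by an inheritance label: biallelic, hemizygous,
# compound-het and inherited heterozygous candidates belong to the
# recessive search and are judged under the recessive allele-frequency
# ceiling; de novo and unresolved variants under the dominant one.
mode_for_label <- function(label) {
  ifelse(label %in% c("hom_recessive", "hemizygous", "comp_het_partner",
                      "comp_het", "inherited_het_mat", "inherited_het_pat",
                      "recessive"),
         "recessive", "dominant")
}
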