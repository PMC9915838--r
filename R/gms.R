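# Panel-based tiering (Genome Medicine Service workflow) ------------------

#' Panel-based pre-filter for one variant
#'
#' A variant passes the pre-filter when its maximum population allele
#' frequency is below the mode threshold (dominant < 0.001, recessive
#' < 0.01), some transcript consequence is coding +/- 8 bp and not
#' synonymous, proband genotype quality exceeds 30 and the call has
#' FILTER = PASS. Gene-agnostic candidates (de novo coding variants and
#' top-ranked Exomiser hits) bypass the genotype-quality and FILTER
#' requirements — they are not filtered on quality.
#'
#' @param variant One-row variant table.
#' @param trio Genotype fields source; defaults to the variant row.
#' @param label Inheritance label from [classify_trio()].
#' @param cfg A [filter_config()] (gms strategy).
#' @param mode `"dominant"` or `"recessive"`; defaults from the label.
#' @return List with `pass` (full pre-filter), `core` (frequency +
#'   consequence rules only, the part gene-agnostic candidates must still
#'   meet), `quality` (GQ + FILTER) and `reasons`.
#' @export
gms_prefilter <- function(variant, trio = variant, label = "uninformative",
                          cfg = filter_config("gms"), mode = NULL) {
  if (is.null(mode)) mode <- mode_for_label(label)
  reasons <- character()
  af <- max_af(variant)
  af_lim <- af_max_for_mode(cfg, mode)
  af_ok <- af < af_lim
  if (!af_ok) reasons <- c(reasons, sprintf("af(%.3g>=%g)", af, af_lim))

  hits <- consequence_hits(variant[["consequences"]], cfg$coding_window_bp)
  csq_ok <- nrow(hits) > 0
  if (!csq_ok) reasons <- c(reasons, "consequence")

  pro <- if (is.null(trio)) list(gt = NA, gq = NA) else member_fields(trio, "pro")
  gq_ok <- is.na(pro$gq) || pro$gq > cfg$gq_min
  if (!gq_ok) reasons <- c(reasons, "gq")
  pass_ok <- !cfg$require_pass || is.na(variant[["filter_status"]]) ||
    variant[["filter_status"]] == "PASS"
  if (!pass_ok) reasons <- c(reasons, "filter_status")

  core <- af_ok && csq_ok
  list(pass = core && gq_ok && pass_ok, core = core,
       quality = gq_ok && pass_ok, reasons = reasons)
}

#' Assign a panel tier to one variant
#'
#' Tier definitions:
#' * `TIER1` — predicted loss-of-function or de novo variant in a green
#'   gene on an applied panel;
#' * `TIER2` — other coding +/- 8 bp non-synonymous variant in a green
#'   panel gene;
#' * `GENE_AGNOSTIC_DENOVO` — de novo coding variant in any gene;
#' * `GENE_AGNOSTIC_EXOMISER` — Exomiser rank <= 3 with score >= 0.95;
#' * `UNTIERED` otherwise.
#'
#' Synonymous variants are never tiered, even when predicted to affect
#' splicing. A variant qualifying for several categories is reported once
#' at the highest precedence (TIER1 > TIER2 > gene-agnostic). Panel tiers
#' additionally require the full pre-filter (`quality_ok`); gene-agnostic
#' tiers do not.
#'
#' @param variant One-row variant table.
#' @param label Inheritance label.
#' @param panels A [gene_list()] or list of them (green genes); empty or
#'   `NULL` means only gene-agnostic tiers are possible (a warning is
#'   issued).
#' @param cfg A [filter_config()] (gms strategy).
#' @param quality_ok Did the variant pass the quality half of the
#'   pre-filter?
#' @return List with `tier` and `panel` (the triggering panel name or
#'   `NA`).
#' @export
assign_tier <- function(variant, label, panels, cfg = filter_config("gms"),
                        quality_ok = TRUE) {
  if (is.null(panels) || length(panels) == 0) {
    warning("no gene panels supplied; only gene-agnostic tiers possible")
    green <- data.frame(gene = character(), panel = character())
  } else green <- panel_union(panels)

  hits <- consequence_hits(variant[["consequences"]], cfg$coding_window_bp)
  coding_any <- nrow(hits) > 0
  plain_coding <- any(!hits$splicing) # strictly coding, non-synonymous
  plof <- any(is_lof_term(hits$term, cfg$lof_terms))
  de_novo <- identical(label, "de_novo")
  on_panel <- !is.na(variant[["gene"]]) && variant[["gene"]] %in% green$gene
  panel_name <- if (on_panel) green$panel[match(variant[["gene"]], green$gene)]
                else NA_character_

  if (quality_ok && on_panel && coding_any && (plof || de_novo))
    return(list(tier = "TIER1", panel = panel_name))
  if (quality_ok && on_panel && coding_any)
    return(list(tier = "TIER2", panel = panel_name))
  if (de_novo && plain_coding)
    return(list(tier = "GENE_AGNOSTIC_DENOVO", panel = NA_character_))
  rk <- variant[["exomiser_rank"]]
  sc <- variant[["exomiser_score"]]
  if (!is.na(rk) && !is.na(sc) && rk <= cfg$exomiser_rank_max &&
      sc >= cfg$exomiser_score_min && plain_coding)
    return(list(tier = "GENE_AGNOSTIC_EXOMISER", panel = NA_character_))
  list(tier = "UNTIERED", panel = NA_character_)
}

#' Run the panel-based screen over an annotated trio cohort
#'
#' Applies the pre-filter and tier assignment to every variant. A variant
#' is returned for assessment when it holds a panel tier after the full
#' pre-filter, or a gene-agnostic tier after the frequency/consequence
#' rules alone (the gene-agnostic channel is not filtered on quality).
#'
#' @param cohort Variant table in the canonical layout.
#' @param panels A [gene_list()] or list of them.
#' @param cfg A [filter_config()] (gms strategy).
#' @return A `candidate_set` whose `variants` carry `label`, `tier`,
#'   `panel`, `trail` and `key` columns; untiered variants are dropped.
#' @export
gms_screen <- function(cohort, panels, cfg = filter_config("gms")) {
  cohort <- validate_variants(cohort)
  n_input <- nrow(cohort)
  labels <- if (n_input) classify_trio(cohort$pro_gt, cohort$mat_gt,
                                       cohort$pat_gt, cohort$chrom,
                                       cohort$pos, cohort$proband_sex)
            else character()
  rows <- lapply(seq_len(n_input), function(i) {
    v <- cohort[i, , drop = FALSE]
    pf <- gms_prefilter(v, v, labels[i], cfg)
    if (!pf$core) return(NULL)
    ta <- assign_tier(v, labels[i], panels, cfg, quality_ok = pf$quality)
    if (ta$tier == "UNTIERED") return(NULL)
    v$label <- labels[i]
    v$tier <- ta$tier
    v$panel <- ta$panel
    v$trail <- paste0("prefilter:", if (pf$pass) "pass" else "bypass",
                      ",tier:", ta$tier)
    v
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) {
    out <- do.call(rbind, rows)
  } else {
    out <- cohort[0, , drop = FALSE]
    out$label <- character(0)
    out$tier <- character(0)
    out$panel <- character(0)
    out$trail <- character(0)
  }
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out$strategy <- rep("gms", nrow(out))
  rownames(out) <- NULL
  candidate_set("gms", out, n_input)
}

#' Tier A rule for copy-number variants
#'
#' A CNV qualifies for Tier A when it is larger than 10 kb and overlaps
#' (shares at least one base with) either a curated pathogenic region
#' relevant to an applied panel or the interval of a green gene on an
#' applied panel.
#'
#' @param cnv Data frame of CNV calls with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param panel_genes Data frame of green-gene intervals (`chrom`,
#'   `start`, `end`), or `NULL`.
#' @param curated_regions Data frame of curated pathogenic region
#'   intervals, or `NULL`.
#' @param cfg A [filter_config()] (gms strategy) for the size threshold.
#' @return Logical vector, one element per CNV.
#' @export
tier_a_cnv <- function(cnv, panel_genes = NULL, curated_regions = NULL,
                       cfg = filter_config("gms")) {
  stopifnot(all(cnv$end >= cnv$start))
  size <- cnv$end - cnv$start + 1
  overlaps_any <- function(chrom, start, end, tab) {
    if (is.null(tab) || nrow(tab) == 0) return(FALSE)
    any(tab$chrom == chrom & tab$start <= end & tab$end >= start)
  }
  vapply(seq_len(nrow(cnv)), function(i) {
    size[i] > cfg$cnv_min_size_bp &&
      (overlaps_any(cnv$chrom[i], cnv$start[i], cnv$end[i], curated_regions) ||
       overlaps_any(cnv$chrom[i], cnv$start[i], cnv$end[i], panel_genes))
  }, logical(1))
}
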