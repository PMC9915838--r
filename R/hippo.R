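# Panel-agnostic high-pathogenic-potential retention ----------------------

#' ClinVar pathogenic override
#'
#' A variant asserted Pathogenic or Likely pathogenic in ClinVar is
#' retained regardless of inheritance label, in-silico score thresholds or
#' presence in unaffected parents. A hard safety ceiling applies: the
#' maximum population allele frequency must stay below
#' `cfg$override_af_ceiling` (default 0.05).
#'
#' @param variant One-row variant table.
#' @param cfg A [filter_config()] (hippo strategy).
#' @return Logical scalar.
#' @export
clinvar_override <- function(variant, cfg = filter_config("hippo")) {
  cv <- variant[["clinvar"]]
  !is.na(cv) && cv %in% c("P", "LP") && max_af(variant) < cfg$override_af_ceiling
}

#' Apply the panel-agnostic retention rules to one variant
#'
#' Retains a variant when all of the following hold (or the ClinVar
#' pathogenic override fires):
#' 1. maximum population allele frequency below the mode threshold
#'    (dominant < 0.001, recessive < 0.05); absent frequencies count as 0;
#' 2. cohort allele frequency < 0.01;
#' 3. some transcript consequence is coding or within +/- 20 bp of an exon
#'    boundary and is not synonymous ("on any transcript");
#' 4. if the variant qualifies only through splice relevance, SpliceAI
#'    > 0.2 — except canonical splice donor/acceptor disruptions with an
#'    absent SpliceAI score, which are retained as predicted LoF;
#' 5. CADD > 15 when a CADD score is present (absence is not evidence of
#'    benignity: the rule is skipped with a trail note);
#' 6. ClinVar assertion is not Benign/Likely benign;
#' 7. proband allele balance > 0.2 on heterozygous calls (skipped with a
#'    note when depths are unavailable);
#' 8. proband genotype quality > 40 (parents too when
#'    `cfg$gq_all_members`); skipped with a note when unavailable.
#'
#' All threshold comparisons are strict, as printed.
#'
#' @param variant One-row variant table (see [variant_record()]).
#' @param trio Optional list of per-member genotype fields; by default
#'   taken from the variant row itself. Pass `NULL` explicitly when no
#'   genotype-level data exist (quality rules are then skipped with notes).
#' @param label Inheritance label from [classify_trio()].
#' @param cfg A [filter_config()] (hippo strategy).
#' @param mode `"dominant"` or `"recessive"`; defaults from the label.
#' @return List with `retained` (logical), `trail` (character vector of the
#'   rules passed, skipped or failed) and `mode`.
#' @export
hippo_retain <- function(variant, trio = variant, label = "uninformative",
                         cfg = filter_config("hippo"), mode = NULL) {
  if (is.null(mode)) mode <- mode_for_label(label)
  trail <- character()
  fail <- FALSE
  note <- function(x) trail <<- c(trail, x)

  override <- clinvar_override(variant, cfg)
  if (override) note("override:clinvar_path")

  ## (i) population allele frequency
  af <- max_af(variant)
  af_lim <- af_max_for_mode(cfg, mode)
  if (af < af_lim) note(sprintf("af:pass(%.3g<%g)", af, af_lim))
  else { note(sprintf("af:fail(%.3g>=%g)", af, af_lim)); fail <- TRUE }

  ## (ii) cohort allele frequency (absent counts as 0)
  caf <- variant[["cohort_af"]]
  caf <- if (is.null(caf) || is.na(caf)) 0 else as.numeric(caf)
  if (!is.na(cfg$cohort_af_max)) {
    if (caf < cfg$cohort_af_max) note("cohort_af:pass")
    else { note("cohort_af:fail"); fail <- TRUE }
  }

  ## (iii)/(iv) consequence and splice rules
  hits <- consequence_hits(variant[["consequences"]], cfg$coding_window_bp)
  if (nrow(hits) == 0) {
    note("consequence:fail")
    fail <- TRUE
  } else {
    plain_coding <- any(!hits$splicing)
    note(sprintf("consequence:pass(%s@%s)", hits$term[1], hits$transcript[1]))
    if (!plain_coding) {
      sai <- variant[["spliceai"]]
      if (!is.na(cfg$spliceai_min)) {
        if (!is.null(sai) && !is.na(sai)) {
          if (sai > cfg$spliceai_min) note("spliceai:pass")
          else { note("spliceai:fail"); fail <- TRUE }
        } else if (any(hits$canonical)) {
          note("spliceai:absent_canonical_plof")
        } else {
          # absence of a score is not evidence either way
          note("spliceai:absent")
        }
      }
    }
  }

  ## (v) CADD
  cadd <- variant[["cadd"]]
  if (!is.na(cfg$cadd_min)) {
    if (is.null(cadd) || is.na(cadd)) note("cadd:absent")
    else if (cadd > cfg$cadd_min) note("cadd:pass")
    else { note("cadd:fail"); fail <- TRUE }
  }

  ## (vi) ClinVar benign
  cv <- variant[["clinvar"]]
  if (!is.null(cv) && !is.na(cv) && cv %in% c("B", "LB")) {
    note("clinvar:fail(benign)"); fail <- TRUE
  } else note("clinvar:pass")

  ## (vii)/(viii) genotype-level quality
  pro <- if (is.null(trio)) NULL else member_fields(trio, "pro")
  if (is.null(pro) || is.na(pro$gt)) {
    note("allele_balance:unavailable"); note("gq:unavailable")
  } else {
    if (identical(pro$gt, "het")) {
      if (is.na(pro$ref_reads) || is.na(pro$alt_reads)) {
        note("allele_balance:unavailable")
      } else {
        ab <- allele_balance(pro$ref_reads, pro$alt_reads)
        if (!is.nan(ab) && ab > cfg$allele_balance_min) note("allele_balance:pass")
        else { note("allele_balance:fail"); fail <- TRUE }
      }
    }
    gqs <- pro$gq
    if (isTRUE(cfg$gq_all_members)) {
      for (m in c("mat", "pat")) {
        mf <- member_fields(trio, m)
        if (!is.na(mf$gt) && mf$gt != "missing") gqs <- c(gqs, mf$gq)
      }
    }
    if (all(is.na(gqs))) note("gq:unavailable")
    else if (all(gqs[!is.na(gqs)] > cfg$gq_min)) note("gq:pass")
    else { note("gq:fail"); fail <- TRUE }
  }

  retained <- override || !fail
  list(retained = retained, trail = trail, mode = mode)
}

#' Run the full panel-agnostic screen over an annotated trio cohort
#'
#' Mirrors the two searches of the strategy: a de novo/dominant search
#' (de novo variants, plus variants whose parental origin cannot be
#' established because a parent is missing) judged under the dominant
#' allele-frequency ceiling, and a recessive search (homozygous,
#' hemizygous, and compound-heterozygous candidates) under the recessive
#' ceiling. Lone inherited heterozygotes survive only through
#' compound-heterozygous pairing in the same gene or the ClinVar
#' pathogenic override.
#'
#' @param cohort Variant table in the canonical layout, one row per
#'   variant per analysis trio (see [variant_record()]).
#' @param cfg A [filter_config()] (hippo strategy).
#' @param genes Optional [gene_list()]; when given the candidate set is
#'   restricted to it after retention.
#' @return A `candidate_set`: list with `strategy`, `variants` (the
#'   retained rows plus `label`, `mode`, `channel`, `trail`, `key`
#'   columns) and `n_input`.
#' @export
hippo_screen <- function(cohort, cfg = filter_config("hippo"), genes = NULL) {
  cohort <- validate_variants(cohort)
  n_input <- nrow(cohort)
  if (n_input == 0) {
    return(candidate_set("hippo", annotate_candidates(cohort), n_input))
  }
  labels <- classify_trio(cohort$pro_gt, cohort$mat_gt, cohort$pat_gt,
                          cohort$chrom, cohort$pos, cohort$proband_sex)
  keep <- logical(n_input)
  channel <- character(n_input)
  mode <- character(n_input)
  trail <- character(n_input)

  res <- lapply(seq_len(n_input), function(i) {
    v <- cohort[i, , drop = FALSE]
    lab <- labels[i]
    if (clinvar_override(v, cfg)) {
      r <- hippo_retain(v, v, lab, cfg)
      return(list(keep = TRUE, channel = "clinvar_override",
                  mode = r$mode, trail = r$trail))
    }
    if (lab == "de_novo") {
      r <- hippo_retain(v, v, lab, cfg, mode = "dominant")
      return(list(keep = r$retained, channel = "de_novo_dominant",
                  mode = "dominant", trail = r$trail))
    }
    if (lab %in% c("hom_recessive", "hemizygous")) {
      r <- hippo_retain(v, v, lab, cfg, mode = "recessive")
      return(list(keep = r$retained, channel = "recessive",
                  mode = "recessive", trail = r$trail))
    }
    if (lab %in% c("inherited_het_mat", "inherited_het_pat")) {
      r <- hippo_retain(v, v, lab, cfg, mode = "recessive")
      # provisional: requires a compound-het partner to survive
      return(list(keep = r$retained, channel = "comp_het_candidate",
                  mode = "recessive", trail = r$trail))
    }
    if (lab == "uninformative" && !is.na(v$pro_gt) &&
        v$pro_gt %in% c("het", "hom_alt", "hemi") &&
        (is.na(v$mat_gt) || v$mat_gt == "missing" ||
         is.na(v$pat_gt) || v$pat_gt == "missing")) {
      # a missing parental genotype: the record is kept as a dominant
      # candidate but no de novo claim is made
      r <- hippo_retain(v, v, lab, cfg, mode = "dominant")
      return(list(keep = r$retained, channel = "dominant_parent_missing",
                  mode = "dominant", trail = r$trail))
    }
    list(keep = FALSE, channel = "none", mode = mode_for_label(lab),
         trail = "not_a_search_candidate")
  })
  keep <- vapply(res, `[[`, logical(1), "keep")
  channel <- vapply(res, `[[`, character(1), "channel")
  mode <- vapply(res, `[[`, character(1), "mode")
  trail <- vapply(res, function(r) paste(r$trail, collapse = ","), character(1))

  # resolve compound-het candidates per family x gene
  is_cand <- keep & channel == "comp_het_candidate"
  partnered <- logical(n_input)
  if (any(is_cand)) {
    grp_rows <- split(seq_len(n_input),
                      paste(cohort$family, cohort$proband_id, cohort$gene))
    for (rows in grp_rows) {
      rows <- rows[keep[rows] &
                     channel[rows] %in% c("comp_het_candidate",
                                          "de_novo_dominant")]
      if (length(rows) < 2) next
      het <- rows[cohort$pro_gt[rows] == "het"]
      if (length(het) < 2) next
      pairs <- find_compound_hets(labels[het], het)
      if (nrow(pairs)) partnered[unique(c(pairs$id1, pairs$id2))] <- TRUE
    }
  }
  dropped_lone <- is_cand & !partnered
  keep[dropped_lone] <- FALSE
  channel[is_cand & partnered] <- "comp_het"
  labels[is_cand & partnered] <- "comp_het_partner"

  out <- cohort[keep, , drop = FALSE]
  out$label <- labels[keep]
  out$mode <- mode[keep]
  out$channel <- channel[keep]
  out$trail <- trail[keep]
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out$strategy <- rep("hippo", nrow(out))
  rownames(out) <- NULL
  cs <- candidate_set("hippo", out, n_input)
  if (!is.null(genes)) cs <- restrict_to_genes(cs, genes) else cs
}

annotate_candidates <- function(df) {
  for (col in c("label", "mode", "channel", "trail", "key", "strategy")) {
    if (!col %in% names(df)) df[[col]] <- character(0)
  }
  df
}

candidate_set <- function(strategy, variants, n_input) {
  stopifnot(nrow(variants) == 0 || all(nzchar(variants$trail)))
  structure(list(strategy = strategy, variants = variants,
                 n_input = n_input),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set: ", x$strategy, " strategy, ",
      nrow(x$variants), "/", x$n_input, " variants retained>\n", sep = "")
  if (nrow(x$variants)) {
    tab <- table(x$variants$family)
    for (f in names(tab)) cat("  ", f, ": ", tab[[f]], "\n", sep = "")
  }
  invisible(x)
}

#' Per-family candidate counts
#'
#' @param cs A `candidate_set`.
#' @return Data frame with columns `family` and `n`.
#' @export
candidate_counts <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  if (nrow(cs$variants) == 0)
    return(data.frame(family = character(), n = integer()))
  tab <- table(cs$variants$family)
  data.frame(family = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Restrict a candidate set to a gene list
#'
#' Keeps candidates whose gene symbol appears in the list; always a subset
#' of the input.
#'
#' @param cs A `candidate_set`.
#' @param genes A [gene_list()].
#' @return A `candidate_set` with updated counts.
#' @export
restrict_to_genes <- function(cs, genes) {
  stopifnot(inherits(cs, "candidate_set"), inherits(genes, "gene_list"))
  keep <- !is.na(cs$variants$gene) & cs$variants$gene %in% genes$symbols
  out <- cs$variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  candidate_set(cs$strategy, out, cs$n_input)
}
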