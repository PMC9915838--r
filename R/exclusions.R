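# Reporting exclusion criteria --------------------------------------------
#
# Six declarative criteria decide whether a retained candidate is
# reportable. Evidence that requires human judgement (phenotype match, LoF
# curation, read-data review) is consumed as flags, never inferred; an
# unknown evidence field makes the corresponding rule abstain rather than
# fire.

#' Bundle the per-candidate curation evidence
#'
#' All fields default to unknown (`NA`); an unknown field never resolves
#' to `FALSE` — the rules that need it abstain instead.
#'
#' @param gene_disease_moi Established gene-disease mode of inheritance:
#'   `"AD"`, `"AR"`, `"XL"`, or `"none-known"` for a novel gene; `NA` when
#'   unknown.
#' @param second_hit_present Was a second (coding or non-coding) hit found
#'   for a heterozygous variant in a recessive gene?
#' @param phenotype_match Does the established gene-disease phenotype match
#'   the patient?
#' @param tissue_expression_adequate Gene adequately expressed (reference
#'   expression data, e.g. TPM >= 1) in the phenotype-relevant tissue?
#' @param exon_expression_adequate Variant exon adequately expressed
#'   (per-base proportion-expressed-across-transcripts, e.g. pext >= 0.1)?
#' @param pathway_excluded Is the gene explicitly *not* involved in the
#'   relevant biological pathway?
#' @param lof_curation Outcome of manual LoF curation: `"LoF"`,
#'   `"likely_LoF"`, `"not_LoF"`, `"likely_not_LoF"`, or `"n/a"` for
#'   non-LoF variants.
#' @param igv_artefact Did the variant appear artefactual on read-data
#'   visualisation?
#' @return List of class `evidence_bundle`.
#' @export
evidence_bundle <- function(gene_disease_moi = NA_character_,
                            second_hit_present = NA,
                            phenotype_match = NA,
                            tissue_expression_adequate = NA,
                            exon_expression_adequate = NA,
                            pathway_excluded = NA,
                            lof_curation = NA_character_,
                            igv_artefact = NA) {
  if (!is.na(gene_disease_moi) &&
      !gene_disease_moi %in% c("AD", "AR", "XL", "none-known"))
    stop("unknown gene_disease_moi: ", gene_disease_moi)
  if (!is.na(lof_curation) &&
      !lof_curation %in% c("LoF", "likely_LoF", "not_LoF",
                           "likely_not_LoF", "n/a"))
    stop("unknown lof_curation: ", lof_curation)
  structure(list(gene_disease_moi = gene_disease_moi,
                 second_hit_present = second_hit_present,
                 phenotype_match = phenotype_match,
                 tissue_expression_adequate = tissue_expression_adequate,
                 exon_expression_adequate = exon_expression_adequate,
                 pathway_excluded = pathway_excluded,
                 lof_curation = lof_curation,
                 igv_artefact = igv_artefact),
            class = "evidence_bundle")
}

#' Evaluate the reporting exclusion criteria for one candidate
#'
#' The criteria, in order (the lowest firing index is recorded):
#' 1. heterozygous variant in a known autosomal recessive disease gene,
#'    not part of a compound-het pair, and no second hit was identified;
#' 2. variant in a known disease gene not associated with the presented
#'    phenotype — unless the variant is Pathogenic/Likely pathogenic in
#'    ClinVar;
#' 3. known disease gene with inadequate tissue- or exon-level expression;
#' 4. novel gene with inadequate expression, or explicitly excluded from
#'    the relevant biological pathway;
#' 5. predicted loss-of-function variant curated as not LoF / likely not
#'    LoF;
#' 6. variant artefactual on read-data visualisation.
#'
#' A rule whose applicability is established but whose deciding evidence is
#' unknown abstains and is listed in `abstained`.
#'
#' @param variant One-row variant table (for the ClinVar assertion and
#'   consequence terms).
#' @param label Inheritance label from [classify_trio()].
#' @param evidence An [evidence_bundle()].
#' @param comp_het Is the variant one member of a compound-het pair?
#' @return List with `verdict` (`"reportable"`/`"excluded"`), `criterion`
#'   (1-6 or `NA`) and `abstained` (character vector of abstaining rules).
#' @export
evaluate_exclusions <- function(variant, label, evidence,
                                comp_het = identical(label,
                                                     "comp_het_partner")) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  ev <- evidence
  abstained <- character()
  fire <- NA_integer_
  moi <- ev$gene_disease_moi
  known_gene <- if (is.na(moi)) NA else moi != "none-known"
  clinvar <- variant[["clinvar"]]
  clinvar_plp <- !is.null(clinvar) && !is.na(clinvar) &&
    clinvar %in% c("P", "LP")
  hits <- csq_unpack(variant[["consequences"]])
  plof <- any(is_lof_term(hits$term))
  is_het <- !is.na(variant[["pro_gt"]]) && variant[["pro_gt"]] == "het"

  # 1: lone het in a recessive gene without a second hit
  if (is_het && !comp_het) {
    if (is.na(moi)) abstained <- c(abstained, "criterion_1")
    else if (moi == "AR") {
      if (is.na(ev$second_hit_present)) abstained <- c(abstained, "criterion_1")
      else if (!ev$second_hit_present) fire <- min(fire, 1L, na.rm = TRUE)
    }
  }
  # 2: phenotype mismatch in a known disease gene (ClinVar P/LP exempt)
  if (!clinvar_plp) {
    if (is.na(known_gene)) abstained <- c(abstained, "criterion_2")
    else if (known_gene) {
      if (is.na(ev$phenotype_match)) abstained <- c(abstained, "criterion_2")
      else if (!ev$phenotype_match) fire <- min(fire, 2L, na.rm = TRUE)
    }
  }
  # 3: poorly expressed known disease gene
  if (is.na(known_gene)) abstained <- c(abstained, "criterion_3")
  else if (known_gene) {
    inadequate <- c(ev$tissue_expression_adequate,
                    ev$exon_expression_adequate)
    if (any(!inadequate, na.rm = TRUE)) fire <- min(fire, 3L, na.rm = TRUE)
    else if (anyNA(inadequate)) abstained <- c(abstained, "criterion_3")
  }
  # 4: novel gene poorly expressed or outside the relevant pathway
  if (is.na(known_gene)) abstained <- c(abstained, "criterion_4")
  else if (!known_gene) {
    bad <- c(!ev$tissue_expression_adequate, !ev$exon_expression_adequate,
             ev$pathway_excluded)
    if (any(bad, na.rm = TRUE)) fire <- min(fire, 4L, na.rm = TRUE)
    else if (anyNA(bad)) abstained <- c(abstained, "criterion_4")
  }
  # 5: predicted LoF curated as not LoF
  if (plof) {
    if (is.na(ev$lof_curation)) abstained <- c(abstained, "criterion_5")
    else if (ev$lof_curation %in% c("not_LoF", "likely_not_LoF"))
      fire <- min(fire, 5L, na.rm = TRUE)
  }
  # 6: artefact on read visualisation
  if (is.na(ev$igv_artefact)) abstained <- c(abstained, "criterion_6")
  else if (ev$igv_artefact) fire <- min(fire, 6L, na.rm = TRUE)

  if (!is.na(fire)) list(verdict = "excluded", criterion = fire,
                         abstained = abstained)
  else list(verdict = "reportable", criterion = NA_integer_,
            abstained = abstained)
}

#' Evaluate exclusions across a candidate set
#'
#' @param cs A `candidate_set` (from [hippo_screen()] or [gms_screen()]).
#' @param evidence Named list of [evidence_bundle()]s keyed by variant key
#'   (`chrom:pos:ref:alt`), or a data frame with a `key` column plus the
#'   evidence fields. Candidates without evidence are evaluated with an
#'   all-unknown bundle (every rule abstains) and flagged.
#' @return Data frame: one row per candidate with `key`, `family`, `gene`,
#'   `verdict`, `criterion`, `abstained` (semicolon-packed) and
#'   `evidence_missing`.
#' @export
evaluate_candidates <- function(cs, evidence = list()) {
  stopifnot(inherits(cs, "candidate_set"))
  if (is.data.frame(evidence)) evidence <- evidence_from_table(evidence)
  v <- cs$variants
  rows <- lapply(seq_len(nrow(v)), function(i) {
    key <- v$key[i]
    ev <- evidence[[key]]
    missing_ev <- is.null(ev)
    if (missing_ev) ev <- evidence_bundle()
    d <- evaluate_exclusions(v[i, , drop = FALSE], v$label[i], ev)
    data.frame(key = key, family = v$family[i], gene = v$gene[i],
               verdict = d$verdict, criterion = d$criterion,
               abstained = paste(d$abstained, collapse = ";"),
               evidence_missing = missing_ev, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(key = character(), family = character(),
                      gene = character(), verdict = character(),
                      criterion = integer(), abstained = character(),
                      evidence_missing = logical()))
  do.call(rbind, rows)
}

evidence_from_table <- function(df) {
  stopifnot("key" %in% names(df))
  fields <- setdiff(names(formals(evidence_bundle)), character())
  out <- lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(fields, names(df)), drop = FALSE])
    do.call(evidence_bundle, lapply(args, function(x) x[[1]]))
  })
  names(out) <- df$key
  out
}

#' Count reportable candidates per family
#'
#' @param decisions Output of [evaluate_candidates()].
#' @return Data frame with `family`, `n_reportable` and `n_excluded`.
#' @export
reportable_count <- function(decisions) {
  if (nrow(decisions) == 0)
    return(data.frame(family = character(), n_reportable = integer(),
                      n_excluded = integer()))
  fams <- sort(unique(decisions$family))
  data.frame(
    family = fams,
    n_reportable = vapply(fams, function(f) {
      sum(decisions$family == f & decisions$verdict == "reportable")
    }, integer(1)),
    n_excluded = vapply(fams, function(f) {
      sum(decisions$family == f & decisions$verdict == "excluded")
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
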