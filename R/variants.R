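# Normalised variant records ---------------------------------------------
#
# A cohort is a plain data frame with one row per bi-allelic variant per
# analysis trio. Annotations that are genuinely absent are NA, never 0: a
# missing CADD score is distinguishable from CADD = 0.

.AF_SOURCES <- c("af_gnomad_exomes", "af_gnomad_genomes", "af_topmed",
                 "af_exac", "af_1000g")

.CLINVAR_LEVELS <- c("P", "LP", "VUS", "LB", "B", "conflicting")

.GT_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi", "missing")

cohort_columns <- function() {
  c("family", "proband_id", "chrom", "pos", "ref", "alt", "gene",
    "consequences", .AF_SOURCES, "cohort_af", "cadd", "revel", "spliceai",
    "clinvar", "exomiser_rank", "exomiser_score", "filter_status",
    "proband_sex",
    "pro_gt", "pro_ref_reads", "pro_alt_reads", "pro_gq",
    "mat_gt", "mat_ref_reads", "mat_alt_reads", "mat_gq",
    "pat_gt", "pat_ref_reads", "pat_alt_reads", "pat_gq")
}

#' Construct one normalised annotated variant record
#'
#' Convenience constructor for a single-row variant table in the package's
#' canonical layout. Unsupplied annotations are absent (`NA`), not zero.
#' Genotypes are coded `hom_ref`, `het`, `hom_alt`, `hemi` or `missing`;
#' an absent family member (duo support) is `NA`.
#'
#' @param chrom,pos,ref,alt Variant site, 1-based VCF convention, bi-allelic.
#' @param gene Gene symbol.
#' @param consequence Consequence term(s), one per transcript.
#' @param transcript Transcript id(s), recycled against `consequence`.
#' @param distance Distance in bp to the nearest exon boundary per
#'   transcript (0 for exonic consequences).
#' @param af Shorthand setting every population allele-frequency source at
#'   once; individual sources can be overridden.
#' @param af_gnomad_exomes,af_gnomad_genomes,af_topmed,af_exac,af_1000g
#'   Per-source population allele fractions in \[0, 1\].
#' @param cohort_af Within-cohort allele fraction.
#' @param cadd PHRED-scaled CADD score (>= 0) or `NA`.
#' @param revel REVEL score in \[0, 1\] or `NA` (carried, never filtered on).
#' @param spliceai Maximum SpliceAI delta score in \[0, 1\] or `NA`.
#' @param clinvar One of `P`, `LP`, `VUS`, `LB`, `B`, `conflicting`, or `NA`.
#' @param exomiser_rank,exomiser_score Consumed Exomiser annotations.
#' @param filter_status VCF FILTER column value.
#' @param family,proband_id Analysis-unit identifiers.
#' @param proband_sex `"M"`, `"F"` or `NA`.
#' @param pro_gt,mat_gt,pat_gt Member genotype codes.
#' @param pro_ref_reads,pro_alt_reads,pro_gq Proband allele depths and
#'   genotype quality; `mat_*`/`pat_*` likewise for the parents.
#' @return One-row data frame in the canonical cohort layout.
#' @export
variant_record <- function(chrom, pos, ref, alt, gene = NA_character_,
                           consequence = "missense", transcript = "tx1",
                           distance = 0,
                           af = NA_real_,
                           af_gnomad_exomes = af, af_gnomad_genomes = af,
                           af_topmed = af, af_exac = af, af_1000g = af,
                           cohort_af = NA_real_,
                           cadd = NA_real_, revel = NA_real_,
                           spliceai = NA_real_,
                           clinvar = NA_character_,
                           exomiser_rank = NA_integer_,
                           exomiser_score = NA_real_,
                           filter_status = "PASS",
                           family = "FAM", proband_id = "P",
                           proband_sex = NA_character_,
                           pro_gt = "het", mat_gt = "hom_ref",
                           pat_gt = "hom_ref",
                           pro_ref_reads = NA_real_, pro_alt_reads = NA_real_,
                           pro_gq = NA_real_,
                           mat_ref_reads = NA_real_, mat_alt_reads = NA_real_,
                           mat_gq = NA_real_,
                           pat_ref_reads = NA_real_, pat_alt_reads = NA_real_,
                           pat_gq = NA_real_) {
  n <- max(length(consequence), length(transcript), length(distance))
  csq <- data.frame(transcript = rep_len(as.character(transcript), n),
                    term = rep_len(as.character(consequence), n),
                    distance = rep_len(as.numeric(distance), n))
  rec <- data.frame(
    family = family, proband_id = as.character(proband_id),
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), consequences = csq_pack(csq),
    af_gnomad_exomes = af_gnomad_exomes,
    af_gnomad_genomes = af_gnomad_genomes,
    af_topmed = af_topmed, af_exac = af_exac, af_1000g = af_1000g,
    cohort_af = cohort_af, cadd = cadd, revel = revel, spliceai = spliceai,
    clinvar = as.character(clinvar),
    exomiser_rank = as.integer(exomiser_rank),
    exomiser_score = exomiser_score,
    filter_status = filter_status, proband_sex = as.character(proband_sex),
    pro_gt = pro_gt, pro_ref_reads = pro_ref_reads,
    pro_alt_reads = pro_alt_reads, pro_gq = pro_gq,
    mat_gt = mat_gt, mat_ref_reads = mat_ref_reads,
    mat_alt_reads = mat_alt_reads, mat_gq = mat_gq,
    pat_gt = pat_gt, pat_ref_reads = pat_ref_reads,
    pat_alt_reads = pat_alt_reads, pat_gq = pat_gq,
    stringsAsFactors = FALSE
  )
  validate_variants(rec)
}

#' Validate a variant table against the record invariants
#'
#' Checks positions (>= 1), ref != alt, allele fractions in \[0, 1\],
#' ClinVar vocabulary and genotype codes. Returns the table (with any
#' missing canonical columns added as `NA`) or fails with the offending
#' row.
#'
#' @param df Variant table.
#' @return The validated table, columns in canonical order.
#' @export
validate_variants <- function(df) {
  for (col in setdiff(cohort_columns(), names(df))) df[[col]] <- NA
  df <- df[, cohort_columns(), drop = FALSE]
  if (nrow(df) == 0) return(df)
  bad <- which(df$pos < 1)
  if (length(bad)) stop("pos < 1 at row ", bad[1])
  bad <- which(df$ref == df$alt)
  if (length(bad)) stop("ref == alt at row ", bad[1])
  for (col in c(.AF_SOURCES, "cohort_af")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) stop(col, " outside [0,1] at row ", bad[1])
  }
  bad <- which(!is.na(df$clinvar) & !df$clinvar %in% .CLINVAR_LEVELS)
  if (length(bad)) stop("unknown ClinVar assertion at row ", bad[1], ": ",
                        df$clinvar[bad[1]])
  for (col in c("pro_gt", "mat_gt", "pat_gt")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !v %in% .GT_LEVELS)
    if (length(bad)) stop("unknown genotype code in ", col, " at row ",
                          bad[1], ": ", v[bad[1]])
  }
  rownames(df) <- NULL
  df
}

#' Maximum population allele frequency of a variant record
#'
#' The maximum over all population sources (gnomAD exomes/genomes, TOPMED,
#' ExAC, 1000 Genomes). Absent frequencies count as 0: a variant unseen in
#' every reference population is treated as novel.
#'
#' @param variant One-row variant table (or list with the `af_*` fields).
#' @return Numeric scalar in \[0, 1\].
#' @export
max_af <- function(variant) {
  vals <- unlist(variant[.AF_SOURCES], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) 0 else max(as.numeric(vals))
}

# Number of alternate alleles implied by a genotype code (NA for missing).
n_alt_alleles <- function(gt) {
  unname(c(hom_ref = 0, het = 1, hom_alt = 2, hemi = 1,
           missing = NA_real_)[gt])
}

# Extract one member's genotype fields from a cohort row.
member_fields <- function(variant, member = c("pro", "mat", "pat")) {
  member <- match.arg(member)
  f <- function(suffix) {
    v <- variant[[paste0(member, "_", suffix)]]
    if (is.null(v)) NA else v
  }
  list(gt = f("gt"), ref_reads = as.numeric(f("ref_reads")),
       alt_reads = as.numeric(f("alt_reads")), gq = as.numeric(f("gq")))
}
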