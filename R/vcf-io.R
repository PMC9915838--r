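# VCF / TSV input and output ----------------------------------------------

#' Describe the packed annotation (CSQ-style) INFO field layout
#'
#' Names the INFO key holding VEP-CSQ-style packed annotations, the order
#' of its pipe-separated subfields, and which subfield feeds each
#' normalised record field. The default layout is the one written by
#' [generate_cohort()].
#'
#' @param field INFO key, default `"CSQ"`.
#' @param order Character vector of subfield names in their packed order.
#' @param map Named list: record field -> subfield name. Recognised record
#'   fields: `allele` (optional; per-allele CSQ entries), `gene`,
#'   `transcript`, `consequence`, `distance`, the five `af_*` sources,
#'   `cadd`, `revel`, `spliceai`, `clinvar`, `exomiser_rank`,
#'   `exomiser_score`.
#' @return List of class `csq_field_spec`.
#' @export
csq_field_spec <- function(field = "CSQ",
                           order = c("Gene", "Feature", "Consequence",
                                     "DIST", "gnomADe_AF", "gnomADg_AF",
                                     "TOPMED_AF", "ExAC_AF", "KG_AF",
                                     "CADD", "REVEL", "SpliceAI",
                                     "ClinVar", "ExomiserRank",
                                     "ExomiserScore"),
                           map = list(gene = "Gene", transcript = "Feature",
                                      consequence = "Consequence",
                                      distance = "DIST",
                                      af_gnomad_exomes = "gnomADe_AF",
                                      af_gnomad_genomes = "gnomADg_AF",
                                      af_topmed = "TOPMED_AF",
                                      af_exac = "ExAC_AF",
                                      af_1000g = "KG_AF",
                                      cadd = "CADD", revel = "REVEL",
                                      spliceai = "SpliceAI",
                                      clinvar = "ClinVar",
                                      exomiser_rank = "ExomiserRank",
                                      exomiser_score = "ExomiserScore")) {
  missing_sub <- setdiff(unlist(map), order)
  if (length(missing_sub))
    stop("mapped subfields absent from the declared order: ",
         paste(missing_sub, collapse = ", "))
  structure(list(field = field, order = order, map = map),
            class = "csq_field_spec")
}

vcf_gt_code <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)[[1]]
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(allele_index))
  if (length(alleles) == 1) {
    if (n_alt == 1) return("hemi")
    return("hom_ref")
  }
  c("hom_ref", "het", "hom_alt")[n_alt + 1]
}

vcf_num <- function(x) {
  x[x %in% c("", ".", "NA")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read an annotated trio VCF into normalised variant records
#'
#' Reads a (possibly gzipped) VCF, checks that every pedigree sample is
#' present, splits multi-allelic sites into bi-allelic records with
#' per-allele depths, unpacks the CSQ-style annotation field, and emits
#' one row per variant allele per analysis trio, in coordinate order.
#' Missing annotations are `NA` (absent), never 0.
#'
#' @param vcf_path Path to the VCF.
#' @param pedigree A [read_pedigree()] object (or PED path).
#' @param csq_spec A [csq_field_spec()].
#' @param cohort_af_field INFO key carrying the within-cohort allele
#'   fraction, or `NULL`.
#' @return Variant table in the canonical layout (see [variant_record()]).
#' @export
read_trio_vcf <- function(vcf_path, pedigree,
                          csq_spec = csq_field_spec(),
                          cohort_af_field = "COHORT_AF") {
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  trios <- analysis_trios(pedigree)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fm <- vcfR::getFIX(vcf)
  if (is.null(dim(fm))) fm <- t(fm)  # single-record VCF yields a vector
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  # analyse the trios whose proband was sequenced in this VCF (a cohort
  # pedigree may span several per-family files); a listed parent missing
  # from the file is fatal
  trios <- trios[trios$proband %in% samples, , drop = FALSE]
  if (nrow(trios) == 0)
    stop("no pedigree proband found among VCF samples: ",
         paste(samples, collapse = ", "))
  need <- unique(stats::na.omit(unlist(trios[c("proband", "father",
                                               "mother")])))
  absent <- setdiff(need, samples)
  if (length(absent))
    stop("pedigree sample(s) missing from VCF: ",
         paste(absent, collapse = ", "))

  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(vcf, "GQ"), error = function(e) NULL)
  csq_raw <- vcfR::extract.info(vcf, csq_spec$field)
  cohort_af <- if (!is.null(cohort_af_field))
    vcf_num(vcfR::extract.info(vcf, cohort_af_field)) else
      rep(NA_real_, nrow(fix))

  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ann <- parse_csq(csq_raw[i], csq_spec, line = i)
    for (k in seq_along(alts)) {
      ann_k <- csq_for_allele(ann, alts[k], csq_spec)
      for (t in seq_len(nrow(trios))) {
        rec <- assemble_record(fix, i, alts, k, ann_k, csq_spec,
                               cohort_af[i], trios[t, ], gt, ad, gq)
        out[[length(out) + 1]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$alt, res$proband_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  validate_variants(res)
}

parse_csq <- function(raw, spec, line) {
  if (is.na(raw) || !nzchar(raw)) return(NULL)
  entries <- strsplit(strsplit(raw, ",", fixed = TRUE)[[1]], "|",
                      fixed = TRUE)
  n_fields <- length(spec$order)
  ok <- vapply(entries, function(e) length(e) <= n_fields, logical(1))
  if (!all(ok))
    stop("unparseable annotation field at VCF record ", line, ": ",
         raw)
  mat <- t(vapply(entries, function(e) {
    c(e, rep("", n_fields - length(e)))
  }, character(n_fields)))
  colnames(mat) <- spec$order
  as.data.frame(mat, stringsAsFactors = FALSE)
}

csq_for_allele <- function(ann, alt, spec) {
  if (is.null(ann)) return(NULL)
  if (!is.null(spec$map$allele)) {
    keep <- ann[[spec$map$allele]] == alt
    if (any(keep)) return(ann[keep, , drop = FALSE])
  }
  ann
}

member_from_vcf <- function(sample, row, allele_index, gt, ad, gq) {
  if (is.na(sample))
    return(list(gt = NA_character_, ref_reads = NA_real_,
                alt_reads = NA_real_, gq = NA_real_))
  g <- vcf_gt_code(gt[row, sample], allele_index)
  depths <- c(0, 0)
  if (!is.null(ad) && !is.na(ad[row, sample])) {
    parts <- vcf_num(strsplit(ad[row, sample], ",", fixed = TRUE)[[1]])
    depths <- c(parts[1], parts[allele_index + 1])
    depths[is.na(depths)] <- 0
  }
  q <- if (is.null(gq)) NA_real_ else vcf_num(gq[row, sample])
  list(gt = g, ref_reads = depths[1], alt_reads = depths[2], gq = q)
}

assemble_record <- function(fix, i, alts, k, ann, spec, cohort_af, trio,
                            gt, ad, gq) {
  pro <- member_from_vcf(trio$proband, i, k, gt, ad, gq)
  mat <- member_from_vcf(trio$mother, i, k, gt, ad, gq)
  pat <- member_from_vcf(trio$father, i, k, gt, ad, gq)
  sub <- function(field) {
    key <- spec$map[[field]]
    if (is.null(ann) || is.null(key)) return(NULL)
    v <- ann[[key]]
    v[!nzchar(v) | v == "."] <- NA
    v
  }
  csq <- if (is.null(ann)) NA_character_ else csq_pack(data.frame(
    transcript = sub("transcript") %||% paste0("tx", seq_len(nrow(ann))),
    term = sub("consequence") %||% rep(NA_character_, nrow(ann)),
    distance = vcf_num(sub("distance") %||% rep(NA, nrow(ann)))
  ))
  first <- function(field) {
    v <- sub(field)
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_character_ else v[1]
  }
  rec <- variant_record(
    chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]), ref = fix$REF[i],
    alt = alts[k], gene = first("gene"),
    family = trio$family, proband_id = trio$proband,
    proband_sex = trio$sex,
    af_gnomad_exomes = vcf_num(first("af_gnomad_exomes")),
    af_gnomad_genomes = vcf_num(first("af_gnomad_genomes")),
    af_topmed = vcf_num(first("af_topmed")),
    af_exac = vcf_num(first("af_exac")),
    af_1000g = vcf_num(first("af_1000g")),
    cadd = vcf_num(first("cadd")),
    revel = vcf_num(first("revel")),
    spliceai = vcf_num(first("spliceai")),
    clinvar = first("clinvar"),
    exomiser_rank = as.integer(vcf_num(first("exomiser_rank"))),
    exomiser_score = vcf_num(first("exomiser_score")),
    filter_status = if (is.na(fix$FILTER[i]) || fix$FILTER[i] == ".")
      NA_character_ else fix$FILTER[i],
    cohort_af = cohort_af,
    pro_gt = pro$gt, pro_ref_reads = pro$ref_reads,
    pro_alt_reads = pro$alt_reads, pro_gq = pro$gq,
    mat_gt = mat$gt, mat_ref_reads = mat$ref_reads,
    mat_alt_reads = mat$alt_reads, mat_gq = mat$gq,
    pat_gt = pat$gt, pat_ref_reads = pat$ref_reads,
    pat_alt_reads = pat$alt_reads, pat_gq = pat$gq
  )
  rec$consequences <- csq
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Candidate tables --------------------------------------------------------

.CHARACTER_COLS <- c("family", "proband_id", "chrom", "ref", "alt", "gene",
                     "consequences", "clinvar", "filter_status",
                     "proband_sex", "pro_gt", "mat_gt", "pat_gt", "label",
                     "mode", "channel", "trail", "key", "strategy", "tier",
                     "panel", "variant", "consequence")

.NUMERIC_COLS <- c("pos", "af_gnomad_exomes", "af_gnomad_genomes",
                   "af_topmed", "af_exac", "af_1000g", "cohort_af",
                   "cadd", "revel", "spliceai", "exomiser_score",
                   "pro_ref_reads", "pro_alt_reads", "pro_gq",
                   "mat_ref_reads", "mat_alt_reads", "mat_gq",
                   "pat_ref_reads", "pat_alt_reads", "pat_gq")

#' Write a candidate set (or variant table) to TSV
#'
#' Deterministic column order (canonical record columns first, extras in
#' their existing order); round-trips losslessly through
#' [read_candidates()]. An empty set yields a header-only file.
#'
#' @param cs A `candidate_set` or a plain variant table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cs, path) {
  df <- if (inherits(cs, "candidate_set")) cs$variants else cs
  lead <- intersect(cohort_columns(), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a candidate TSV written by [write_candidates()]
#'
#' @param path TSV path.
#' @return Data frame with the canonical column types restored.
#' @export
read_candidates <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  classes <- ifelse(hdr %in% .CHARACTER_COLS, "character",
                    ifelse(hdr %in% .NUMERIC_COLS, "numeric",
                           ifelse(hdr == "exomiser_rank", "integer", NA)))
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = classes, check.names = FALSE)
  df
}

#' Attach or override annotations from a sidecar TSV
#'
#' The second annotation-ingestion dialect: a TSV keyed by
#' `chrom`, `pos`, `ref`, `alt` whose remaining columns use the canonical
#' record names (e.g. `cadd`, `clinvar`, `af_gnomad_exomes`,
#' `consequences`). Matching rows overwrite the corresponding fields of
#' the variant table; unmatched variants are left untouched.
#'
#' @param cohort Variant table in the canonical layout.
#' @param annotations Data frame or TSV path.
#' @return The annotated variant table.
#' @export
attach_annotations <- function(cohort, annotations) {
  ann <- if (is.character(annotations))
    read.table(annotations, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE,
               colClasses = c(chrom = "character")) else annotations
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(ann)))
  key_c <- variant_key(cohort$chrom, cohort$pos, cohort$ref, cohort$alt)
  key_a <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  idx <- match(key_c, key_a)
  for (col in setdiff(names(ann), c("chrom", "pos", "ref", "alt"))) {
    if (!col %in% cohort_columns()) next
    hit <- !is.na(idx)
    cohort[[col]][hit] <- ann[[col]][idx[hit]]
  }
  validate_variants(cohort)
}
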