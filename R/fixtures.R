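# Packaged study summary tables -------------------------------------------
#
# Machine-readable transcriptions of the summary tables of a published
# nine-family rare-disease cohort in which every family underwent both
# panel-agnostic exome triage and panel-based clinical genome analysis.
# The files are checksummed so a silent edit of the transcription is
# fatal rather than quietly shifting the comparison statistics.

.FIXTURE_MD5 <- c(
  cohort_family_counts.tsv = "db7050aad11348e9fb54460add26805f",
  cohort_reported_exome.tsv = "778d0a88c28511fcab61114d011a6067",
  cohort_reported_gms.tsv = "36ceab8634ff394d7b5751be7da9c42c"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "hippotrio")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Load the packaged cohort summary tables
#'
#' Returns the bundled per-family assessment counts and the two
#' reported-variant tables of the example nine-family comparison cohort:
#' 17 variants reported by the panel-agnostic exome arm (with their
#' printed annotations — gnomAD AF, CADD, REVEL, ClinVar, allele counts)
#' and 5 variants reported by the panel-based clinical genome arm.
#'
#' @param check Verify file checksums (fatal on mismatch).
#' @return List with data frames `family_counts`, `exome_reported` and
#'   `gms_reported`.
#' @export
study_tables <- function(check = TRUE) {
  paths <- vapply(names(.FIXTURE_MD5), fixture_path, character(1))
  if (check) {
    got <- tools::md5sum(paths)
    bad <- names(.FIXTURE_MD5)[got != .FIXTURE_MD5]
    if (length(bad))
      stop("checksum mismatch on packaged fixture(s): ",
           paste(bad, collapse = ", "))
  }
  read_fixture <- function(p, char_cols) {
    hdr <- NULL
    con <- file(p); lines <- readLines(con); close(con)
    hdr_line <- lines[!startsWith(lines, "#")][1]
    hdr <- strsplit(hdr_line, "\t", fixed = TRUE)[[1]]
    classes <- ifelse(hdr %in% char_cols, "character", NA)
    read.table(p, header = TRUE, sep = "\t", quote = "",
               comment.char = "#", stringsAsFactors = FALSE,
               na.strings = c("NA"), colClasses = classes)
  }
  char_cols <- c("family", "proband", "variant", "gene", "consequence",
                 "hgvsc", "hgvsp", "clinvar", "acmg", "inheritance",
                 "class", "gms_report", "note", "s2_id", "s3_id",
                 "returned_by_gms")
  list(
    family_counts = read_fixture(paths[["cohort_family_counts.tsv"]],
                                 char_cols),
    exome_reported = read_fixture(paths[["cohort_reported_exome.tsv"]],
                                  char_cols),
    gms_reported = read_fixture(paths[["cohort_reported_gms.tsv"]],
                                char_cols)
  )
}

#' Build variant records from the packaged reported-variants table
#'
#' Converts each printed row into a canonical annotated record: the
#' gnomAD column feeds the population allele-frequency sources, the
#' consequence term is taken on a single transcript (exonic, distance 0),
#' and the inheritance context maps to a search mode (`comp_het` rows are
#' judged recessive, all others dominant). Parental allele counts
#' reconstruct the parent genotypes where both samples are present.
#'
#' @param exome_reported The `exome_reported` table from [study_tables()].
#' @return List with `variants` (canonical variant table) and `modes`
#'   (character vector of search modes, parallel to rows).
#' @export
reported_variant_records <- function(exome_reported) {
  rows <- lapply(seq_len(nrow(exome_reported)), function(i) {
    r <- exome_reported[i, ]
    site <- strsplit(r$variant, ":", fixed = TRUE)[[1]]
    ac_gt <- function(ac) {
      if (is.na(ac)) return(NA_character_)
      c("hom_ref", "het", "hom_alt")[as.integer(ac) + 1]
    }
    variant_record(
      chrom = site[1], pos = as.numeric(site[2]), ref = site[3],
      alt = site[4], gene = r$gene,
      consequence = r$consequence, distance = 0,
      af = r$gnomad_af, cadd = r$cadd, revel = r$revel,
      clinvar = if (is.na(r$clinvar)) NA_character_ else r$clinvar,
      family = r$family, proband_id = as.character(r$proband),
      pro_gt = ac_gt(r$p_ac), mat_gt = ac_gt(r$s2_ac),
      pat_gt = ac_gt(r$s3_ac)
    )
  })
  variants <- do.call(rbind, rows)
  modes <- ifelse(exome_reported$inheritance == "comp_het",
                  "recessive", "dominant")
  list(variants = variants, modes = modes)
}
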