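# Trio inheritance classification -----------------------------------------

#' Default GRCh38 X-chromosome pseudo-autosomal regions
#'
#' @return Data frame of PAR intervals (1-based inclusive) on X.
#' @export
par_regions_grch38 <- function() {
  data.frame(region = c("PAR1", "PAR2"),
             start = c(10001, 155701383),
             end = c(2781479, 156030895))
}

is_x_nonpar <- function(chrom, pos, par = par_regions_grch38()) {
  onx <- sub("^chr", "", as.character(chrom)) == "X"
  if (!onx) return(FALSE)
  if (is.na(pos)) return(TRUE)
  !any(pos >= par$start & pos <= par$end)
}

#' Classify the segregation pattern of a variant within a trio
#'
#' Labels, in order of precedence:
#' * `de_novo` — proband carries at least one alternate allele and both
#'   parents are present with homozygous-reference genotypes.
#' * `hemizygous` — X non-PAR site, male proband carrying the alternate,
#'   mother heterozygous, father not a carrier (or absent).
#' * `hom_recessive` — proband homozygous alternate and every parent with
#'   genotype data carries at most one alternate allele.
#' * `inherited_het_mat` / `inherited_het_pat` — heterozygous proband with
#'   exactly one carrier parent (transmission observable).
#' * `uninformative` — everything else: proband missing or reference,
#'   a parental genotype missing where it would be needed (no de novo call
#'   is possible with an absent parent), or both parents carriers of a
#'   heterozygous proband allele (origin ambiguous).
#'
#' Vectorised over its arguments.
#'
#' @param pro_gt,mat_gt,pat_gt Genotype codes (`hom_ref`, `het`, `hom_alt`,
#'   `hemi`, `missing`); `NA` for an absent family member.
#' @param chrom Chromosome label (for X handling).
#' @param pos Position, used to exclude pseudo-autosomal regions.
#' @param proband_sex `"M"`, `"F"` or `NA`.
#' @param par Pseudo-autosomal intervals, default GRCh38.
#' @return Character vector of inheritance labels.
#' @export
classify_trio <- function(pro_gt, mat_gt, pat_gt, chrom = "1", pos = NA,
                          proband_sex = NA,
                          par = par_regions_grch38()) {
  n <- max(length(pro_gt), length(mat_gt), length(pat_gt), length(chrom),
           length(pos), length(proband_sex))
  args <- lapply(list(pro_gt, mat_gt, pat_gt, chrom, pos, proband_sex),
                 rep_len, n)
  vapply(seq_len(n), function(i) {
    classify_trio_one(args[[1]][i], args[[2]][i], args[[3]][i],
                      args[[4]][i], args[[5]][i], args[[6]][i], par)
  }, character(1))
}

classify_trio_one <- function(pro, mat, pat, chrom, pos, sex, par) {
  present <- function(gt) !is.na(gt) && gt != "missing"
  if (!present(pro)) return("uninformative")
  pro_alt <- n_alt_alleles(pro)
  if (pro_alt == 0) return("uninformative")

  mat_ok <- present(mat)
  pat_ok <- present(pat)
  mat_alt <- if (mat_ok) n_alt_alleles(mat) else NA_real_
  pat_alt <- if (pat_ok) n_alt_alleles(pat) else NA_real_

  if (mat_ok && pat_ok && mat_alt == 0 && pat_alt == 0) return("de_novo")

  if (is_x_nonpar(chrom, pos, par) && identical(sex, "M") &&
      mat_ok && mat == "het" && (!pat_ok || pat_alt == 0))
    return("hemizygous")

  if (pro == "hom_alt" &&
      (!mat_ok || mat_alt <= 1) && (!pat_ok || pat_alt <= 1))
    return("hom_recessive")

  if (pro == "het") {
    mat_carrier <- mat_ok && mat_alt >= 1
    pat_carrier <- pat_ok && pat_alt >= 1
    if (mat_carrier && !pat_carrier) return("inherited_het_mat")
    if (pat_carrier && !mat_carrier) return("inherited_het_pat")
  }
  "uninformative"
}

#' Proband allele balance
#'
#' Fraction of reads supporting the alternate allele,
#' `alt / (ref + alt)`. A heterozygous call with zero total depth yields
#' `NaN`, which every strict balance threshold treats as failing.
#'
#' @param ref_reads,alt_reads Non-negative read counts.
#' @return Numeric vector of fractions.
#' @export
allele_balance <- function(ref_reads, alt_reads) {
  total <- ref_reads + alt_reads
  alt_reads / total
}

#' Detect compound-heterozygous pairs within one gene
#'
#' Two heterozygous variants in the same gene qualify as a pair when they
#' were transmitted from different parents (one maternal, one paternal —
#' in trans by transmission). A de novo heterozygote may pair with an
#' inherited heterozygote of either origin, since cis configuration cannot
#' be proven without phase. Two variants from the same parent never pair,
#' nor do two de novo variants.
#'
#' @param labels Inheritance labels as returned by [classify_trio()], one
#'   per candidate variant in the gene.
#' @param ids Identifiers parallel to `labels` (defaults to indices).
#' @return Data frame with columns `id1`, `id2` (one row per qualifying
#'   pair, `id1` before `id2` in input order); zero rows when no pair
#'   exists.
#' @export
find_compound_hets <- function(labels, ids = seq_along(labels)) {
  stopifnot(length(labels) == length(ids))
  pairs <- list()
  compatible <- function(a, b) {
    s <- sort(c(a, b))
    (s[1] == "inherited_het_mat" && s[2] == "inherited_het_pat") ||
      (s[1] == "de_novo" &&
         s[2] %in% c("inherited_het_mat", "inherited_het_pat"))
  }
  n <- length(labels)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (compatible(labels[i], labels[j]))
          pairs[[length(pairs) + 1]] <- data.frame(
            id1 = ids[i], id2 = ids[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0)
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}
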