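# Shared builders for handcrafted fixtures, all generated in code.

trio_ped_lines <- function(fam = "FAM1", pro = "PRO", pat = "PAT",
                           mat = "MAT", duo = FALSE) {
  c(paste(fam, pro, if (duo) "0" else pat, mat, "1", "2", sep = "\t"),
    if (!duo) paste(fam, pat, "0", "0", "1", "1", sep = "\t"),
    paste(fam, mat, "0", "0", "2", "1", sep = "\t"))
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Format: ",
           paste(csq_field_spec()$order, collapse = "|"), "\">"),
    "##INFO=<ID=COHORT_AF,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# CSQ entry in the default layout; unspecified subfields are absent.
csq_entry <- function(gene = "GENE1", tx = "tx1", term = "missense",
                      dist = 0, af = 0, cadd = ".", revel = ".",
                      spliceai = ".", clinvar = ".", rank = ".",
                      score = ".") {
  paste(gene, tx, term, dist, af, af, af, af, af, cadd, revel, spliceai,
        clinvar, rank, score, sep = "|")
}

vcf_row <- function(chrom, pos, ref, alt, csq, genotypes,
                    filter = "PASS", cohort_af = 0) {
  paste(c(chrom, pos, ".", ref, alt, ".", filter,
          paste0("CSQ=", csq, ";COHORT_AF=", cohort_af), "GT:AD:GQ",
          genotypes), collapse = "\t")
}

# A high-scoring de novo missense record with clean trio genotypes.
de_novo_record <- function(pos = 1000, alt = "G", gene = "GENE1",
                           consequence = "missense", pro_ref_reads = 12,
                           pro_alt_reads = 10, pro_gq = 99, ...) {
  variant_record(chrom = "1", pos = pos, ref = "C", alt = alt,
                 gene = gene, consequence = consequence, distance = 0,
                 af = 0, cohort_af = 0.0001, cadd = 30,
                 pro_gt = "het", mat_gt = "hom_ref", pat_gt = "hom_ref",
                 pro_ref_reads = pro_ref_reads,
                 pro_alt_reads = pro_alt_reads, pro_gq = pro_gq,
                 mat_ref_reads = 20, mat_alt_reads = 0, mat_gq = 99,
                 pat_ref_reads = 20, pat_alt_reads = 0, pat_gq = 99, ...)
}
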