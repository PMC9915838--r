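# Synthetic annotated trio cohort generator -------------------------------
#
# Emits trio VCF + PED + gene-list fixtures with a per-variant truth table
# (category, expected panel-agnostic verdict, expected panel tier) so that
# every pipeline stage is testable without external data. Coordinates are
# synthetic: each gene occupies its own contig with declared exon
# boundaries, so no genome reference is required and distance-to-exon is
# always computable.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a small rare-disease trio cohort: nine
#' trio families, each carrying a realistic mixture of common benign
#' variation (population AF 0.01-0.5), rare benign variation (AF < 0.001
#' with low CADD), de novo damaging candidates (AF 0, CADD 20-45), one
#' compound-heterozygous pair (AF < 0.01) and one inherited
#' ClinVar-pathogenic variant per family. The seed fully determines the
#' output, byte for byte.
#'
#' @param seed Integer RNG seed.
#' @param n_families Number of trio families.
#' @param n_common_benign,n_rare_benign,n_de_novo,n_comp_het_pairs,n_clinvar_p_inherited
#'   Per-family variant counts by category.
#' @param on_panel_fraction Probability that a gene is green on the
#'   simulated panel.
#' @param gencc_fraction Probability that a gene is on the simulated
#'   strong/definitive disease-gene list.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param gq_range_benign,gq_range_causal Genotype-quality ranges
#'   (uniform integer) for benign and damaging variants.
#' @param nonpass_fraction Fraction of records with a non-PASS FILTER.
#' @param missing_parent_families Indices of families simulated as duos
#'   (father absent). Requesting compound-het pairs in such a family is an
#'   error.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 20230201L, n_families = 9,
                       n_common_benign = 40, n_rare_benign = 15,
                       n_de_novo = 2, n_comp_het_pairs = 1,
                       n_clinvar_p_inherited = 1,
                       on_panel_fraction = 0.5, gencc_fraction = 0.5,
                       depth_mean = 30,
                       gq_range_benign = c(30, 99),
                       gq_range_causal = c(60, 99),
                       nonpass_fraction = 0.05,
                       missing_parent_families = integer(0)) {
  counts <- c(n_families, n_common_benign, n_rare_benign, n_de_novo,
              n_comp_het_pairs, n_clinvar_p_inherited)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_families < 1) stop("need at least one family")
  if (n_comp_het_pairs > 0 && length(missing_parent_families) > 0)
    stop("compound-het simulation requires both parents; family(ies) ",
         paste(missing_parent_families, collapse = ", "),
         " are configured without a father")
  structure(list(seed = as.integer(seed), n_families = n_families,
                 n_common_benign = n_common_benign,
                 n_rare_benign = n_rare_benign, n_de_novo = n_de_novo,
                 n_comp_het_pairs = n_comp_het_pairs,
                 n_clinvar_p_inherited = n_clinvar_p_inherited,
                 on_panel_fraction = on_panel_fraction,
                 gencc_fraction = gencc_fraction,
                 depth_mean = depth_mean,
                 gq_range_benign = gq_range_benign,
                 gq_range_causal = gq_range_causal,
                 nonpass_fraction = nonpass_fraction,
                 missing_parent_families = missing_parent_families),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys match the [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}

.sim_exon_starts <- c(1001, 2001, 3001, 4001, 5001)
.sim_exon_len <- 200
.sim_gene_len <- 6000

# Draw a position and exon distance for a consequence class within a gene.
.sim_position <- function(term) {
  ex <- sample(.sim_exon_starts, 1)
  if (term == "intron") {
    dist <- sample(9:40, 1)
    list(pos = ex + .sim_exon_len - 1 + dist, dist = dist)
  } else {
    list(pos = ex + sample(0:(.sim_exon_len - 1), 1), dist = 0)
  }
}

.sim_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  c(ref, alt)
}

# Genotype realisation for one member: code plus depths and GQ.
.sim_member <- function(gt, depth_mean, gq_range) {
  dp <- max(1L, stats::rpois(1, depth_mean))
  alt <- switch(gt,
                hom_ref = stats::rbinom(1, dp, 0.005),
                het = stats::rbinom(1, dp, 0.5),
                hom_alt = dp - stats::rbinom(1, dp, 0.005))
  list(gt = gt, ref_reads = dp - alt, alt_reads = alt,
       gq = sample(seq(gq_range[1], gq_range[2]), 1))
}

#' Generate a synthetic annotated trio cohort
#'
#' Builds the in-memory cohort table, pedigree, per-variant truth table
#' and simulated gene lists; optionally writes them to disk as one VCF per
#' family plus PED, truth TSV, panel TSV, disease-gene TSV and exon BED.
#'
#' Every emitted variant carries a truth label: its simulation `category`,
#' the verdict the panel-agnostic screen is expected to reach
#' (`expected_hippo`, derived declaratively from the drawn annotations and
#' genotype quality) and the tier the panel-based screen is expected to
#' assign (`expected_gms`).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `cohort` (canonical variant table), `pedigree`,
#'   `truth`, `panel` and `gencc` ([gene_list()]s), `genes` (per-gene
#'   metadata incl. intervals) and, when written, `paths`.
#' @export
generate_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("GENE%04d", gene_counter)
  }

  ped_rows <- list()
  var_rows <- list()
  truth_rows <- list()
  gene_rows <- list()

  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("FAM%02d", f)
    pro <- paste0(fam, "_PRO"); mat <- paste0(fam, "_MAT")
    pat <- paste0(fam, "_PAT")
    duo <- f %in% cfg$missing_parent_families
    sex <- if (f %% 2 == 1) "F" else "M"
    ped_rows[[length(ped_rows) + 1]] <- data.frame(
      family = fam,
      id = c(pro, mat, if (!duo) pat),
      father = c(if (duo) NA_character_ else pat, NA, if (!duo) NA),
      mother = c(mat, NA, if (!duo) NA),
      sex = c(sex, "F", if (!duo) "M"),
      affected = c(TRUE, FALSE, if (!duo) FALSE),
      stringsAsFactors = FALSE)

    plan <- c(rep("common_benign", cfg$n_common_benign),
              rep("rare_benign", cfg$n_rare_benign),
              rep("de_novo_damaging", cfg$n_de_novo),
              rep("clinvar_p_inherited", cfg$n_clinvar_p_inherited))
    specs <- lapply(plan, function(cat) .sim_variant_spec(cat, duo))
    for (p in seq_len(cfg$n_comp_het_pairs)) {
      g <- new_gene()
      specs <- c(specs, .sim_comp_het_specs(g))
    }
    for (s in specs) {
      if (is.null(s$gene)) s$gene <- new_gene()
      built <- .sim_build_variant(s, fam, pro, sex, duo, cfg)
      var_rows[[length(var_rows) + 1]] <- built$variant
      truth_rows[[length(truth_rows) + 1]] <- built$truth
      gene_rows[[length(gene_rows) + 1]] <- s$gene
    }
  }

  genes <- sort(unique(unlist(gene_rows)))
  gene_meta <- data.frame(
    gene = genes, contig = paste0("ctg_", genes),
    start = 1L, end = .sim_gene_len,
    on_panel = stats::runif(length(genes)) < cfg$on_panel_fraction,
    in_gencc = stats::runif(length(genes)) < cfg$gencc_fraction,
    stringsAsFactors = FALSE)

  cohort <- do.call(rbind, var_rows)
  truth <- do.call(rbind, truth_rows)
  truth$on_panel <- gene_meta$on_panel[match(truth$gene, gene_meta$gene)]
  # panel membership refines the expected tier for panel-dependent calls
  truth$expected_gms <- ifelse(
    truth$expected_gms_on_panel != truth$expected_gms_off_panel,
    ifelse(truth$on_panel, truth$expected_gms_on_panel,
           truth$expected_gms_off_panel),
    truth$expected_gms_on_panel)
  truth$expected_gms_on_panel <- NULL
  truth$expected_gms_off_panel <- NULL

  # a compound-het variant survives only when its partner also passes
  ch <- truth$category == "comp_het"
  if (any(ch)) {
    grp <- paste(truth$family, truth$gene)
    for (g in unique(grp[ch])) {
      idx <- which(grp == g & ch)
      truth$expected_hippo[idx] <- all(truth$expected_hippo[idx]) &&
        length(idx) >= 2
    }
  }

  ped <- as_pedigree(do.call(rbind, ped_rows))
  panel <- gene_list(gene_meta$gene[gene_meta$on_panel],
                     name = "sim_panel", provenance = "panelapp_green",
                     allow_empty = TRUE)
  gencc <- gene_list(gene_meta$gene[gene_meta$in_gencc],
                     name = "sim_gencc",
                     provenance = "gencc_strong_definitive",
                     allow_empty = TRUE)
  out <- list(cohort = validate_variants(cohort), pedigree = ped,
              truth = truth, panel = panel, gencc = gencc,
              genes = gene_meta)
  if (!is.null(out_dir)) out$paths <- write_sim_cohort(out, out_dir)
  out
}

# Per-category annotation draws. Values are chosen so the expected
# verdicts are stable: benign variants always carry a (low) CADD score,
# damaging ones exceed every in-silico threshold.
.sim_variant_spec <- function(category, duo) {
  switch(category,
    common_benign = {
      term <- sample(c("missense", "synonymous", "intron"), 1,
                     prob = c(0.5, 0.25, 0.25))
      af <- stats::runif(1, 0.01, 0.5)
      list(category = category, term = term, af = af,
           cohort_af = min(1, af * stats::runif(1, 0.9, 1.1)),
           cadd = stats::runif(1, 0, 10), revel = NA, spliceai = NA,
           clinvar = sample(c(NA, "B", "LB"), 1, prob = c(0.6, 0.25, 0.15)),
           exomiser = FALSE, causal = FALSE,
           pattern = sample(c("het_mat", "het_pat", "hom"), 1,
                            prob = c(0.4, 0.4, 0.2)))
    },
    rare_benign = list(
      category = category, term = "missense",
      af = stats::runif(1, 0, 9e-4), cohort_af = stats::runif(1, 0, 0.009),
      cadd = stats::runif(1, 0, 10), revel = stats::runif(1, 0, 0.3),
      spliceai = NA, clinvar = NA, exomiser = FALSE, causal = FALSE,
      pattern = sample(c("het_mat", "het_pat"), 1)),
    de_novo_damaging = list(
      category = category, term = sample(c("missense", "stop_gained"), 1),
      af = 0, cohort_af = 6.6e-5, cadd = stats::runif(1, 20, 45),
      revel = stats::runif(1, 0.5, 1), spliceai = NA, clinvar = NA,
      exomiser = TRUE, causal = TRUE, pattern = "de_novo"),
    clinvar_p_inherited = list(
      category = category, term = "stop_gained",
      af = stats::runif(1, 0, 5e-4), cohort_af = stats::runif(1, 0, 0.001),
      cadd = stats::runif(1, 0, 45), revel = NA, spliceai = NA,
      clinvar = "P", exomiser = FALSE, causal = TRUE,
      pattern = if (duo) "het_mat" else sample(c("het_mat", "het_pat"), 1))
  )
}

.sim_comp_het_specs <- function(gene) {
  lapply(c("het_mat", "het_pat"), function(p) {
    list(category = "comp_het", gene = gene, term = "missense",
         af = stats::runif(1, 1e-5, 9e-3),
         cohort_af = stats::runif(1, 0, 0.009),
         cadd = stats::runif(1, 16, 40), revel = stats::runif(1, 0.4, 1),
         spliceai = NA, clinvar = NA, exomiser = FALSE, causal = TRUE,
         pattern = p)
  })
}

.sim_build_variant <- function(s, fam, pro_id, sex, duo, cfg) {
  loc <- .sim_position(s$term)
  al <- .sim_alleles()
  gq_range <- if (s$causal) cfg$gq_range_causal else cfg$gq_range_benign
  gts <- switch(s$pattern,
                de_novo = c("het", "hom_ref", "hom_ref"),
                het_mat = c("het", "het", "hom_ref"),
                het_pat = c("het", "hom_ref", "het"),
                hom = c("hom_alt", "het", "het"))
  pro <- .sim_member(gts[1], cfg$depth_mean, gq_range)
  mat <- .sim_member(gts[2], cfg$depth_mean, gq_range)
  pat <- if (duo) NULL else .sim_member(gts[3], cfg$depth_mean, gq_range)
  filter_status <- if (stats::runif(1) < cfg$nonpass_fraction) "LowQual"
                   else "PASS"
  afs <- pmin(1, pmax(0, s$af * stats::runif(5, 0.8, 1.2)))
  if (s$af == 0) afs <- rep(0, 5)
  rank <- if (s$exomiser) sample(1:5, 1) else NA_integer_
  score <- if (s$exomiser) stats::runif(1, 0.9, 0.999) else NA_real_

  v <- variant_record(
    chrom = paste0("ctg_", s$gene), pos = loc$pos, ref = al[1],
    alt = al[2], gene = s$gene,
    consequence = s$term, transcript = paste0(s$gene, "_t1"),
    distance = loc$dist,
    af_gnomad_exomes = afs[1], af_gnomad_genomes = afs[2],
    af_topmed = afs[3], af_exac = afs[4], af_1000g = afs[5],
    cohort_af = s$cohort_af, cadd = s$cadd,
    revel = if (is.na(s$revel)) NA_real_ else s$revel,
    spliceai = if (is.na(s$spliceai)) NA_real_ else s$spliceai,
    clinvar = if (is.na(s$clinvar)) NA_character_ else s$clinvar,
    exomiser_rank = rank, exomiser_score = score,
    filter_status = filter_status,
    family = fam, proband_id = pro_id, proband_sex = sex,
    pro_gt = pro$gt, pro_ref_reads = pro$ref_reads,
    pro_alt_reads = pro$alt_reads, pro_gq = pro$gq,
    mat_gt = mat$gt, mat_ref_reads = mat$ref_reads,
    mat_alt_reads = mat$alt_reads, mat_gq = mat$gq,
    pat_gt = if (duo) NA_character_ else pat$gt,
    pat_ref_reads = if (duo) NA_real_ else pat$ref_reads,
    pat_alt_reads = if (duo) NA_real_ else pat$alt_reads,
    pat_gq = if (duo) NA_real_ else pat$gq)

  truth <- .sim_truth(s, v, duo)
  list(variant = v, truth = truth)
}

# Declarative expected verdicts from the drawn values. The panel-agnostic
# expectation applies the documented retention criteria per category; the
# panel-based expectation is recorded for both panel memberships and
# resolved once gene-panel assignment is known.
.sim_truth <- function(s, v, duo) {
  ab <- allele_balance(v$pro_ref_reads, v$pro_alt_reads)
  quality_hippo <- (v$pro_gt != "het" | (!is.nan(ab) & ab > 0.2)) &
    v$pro_gq > 40
  hippo <- switch(s$category,
    common_benign = FALSE,  # CADD <= 10 (and AF/cohort-AF) always fails
    rare_benign = FALSE,    # CADD <= 10 always fails
    de_novo_damaging = quality_hippo,
    comp_het = quality_hippo,  # provisional; joined with partner below
    clinvar_p_inherited = TRUE  # pathogenic override ignores quality
  )
  gms_quality <- v$pro_gq > 30 & v$filter_status == "PASS"
  coding <- s$term %in% c("missense", "stop_gained")
  af_ok_dom <- max_af(v) < 0.001
  af_ok_rec <- max_af(v) < 0.01
  exomiser_ga <- !is.na(v$exomiser_rank) && !is.na(v$exomiser_score) &&
    v$exomiser_rank <= 3 && v$exomiser_score >= 0.95 && coding
  on_tier <- function(on_panel) {
    if (s$category == "common_benign" || !coding) return("FAIL_PREFILTER")
    if (s$pattern == "de_novo") {
      if (!af_ok_dom) return("FAIL_PREFILTER")
      if (duo) {
        # no de novo call possible without the father: panel tier or the
        # Exomiser gene-agnostic channel only
        if (on_panel && gms_quality)
          return(if (s$term == "stop_gained") "TIER1" else "TIER2")
        return(if (exomiser_ga) "GENE_AGNOSTIC_EXOMISER" else "UNTIERED")
      }
      if (on_panel && gms_quality) return("TIER1")
      return("GENE_AGNOSTIC_DENOVO")
    }
    if (!af_ok_rec) return("FAIL_PREFILTER")
    if (!gms_quality || !on_panel)
      return(if (exomiser_ga) "GENE_AGNOSTIC_EXOMISER" else "UNTIERED")
    if (s$term == "stop_gained") "TIER1" else "TIER2"
  }
  data.frame(family = v$family,
             key = variant_key(v$chrom, v$pos, v$ref, v$alt),
             gene = s$gene, category = s$category, pattern = s$pattern,
             expected_hippo = hippo,
             expected_gms_on_panel = on_tier(TRUE),
             expected_gms_off_panel = on_tier(FALSE),
             stringsAsFactors = FALSE)
}

# On-disk serialisation ----------------------------------------------------

.sim_fmt <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
  }, character(1)))
}

.sim_gt_string <- function(gt) {
  switch(gt, hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
         hemi = "1", missing = "./.", "./.")
}

#' Write a generated cohort to disk
#'
#' Emits one annotated VCF per family, a cohort PED, the truth table, the
#' simulated green-panel and disease-gene TSVs, and a BED of exon
#' intervals (so exon distances can be recomputed independently).
#'
#' @param sim Result of [generate_cohort()].
#' @param out_dir Output directory, created if needed.
#' @return Named list of file paths, invisibly.
#' @export
write_sim_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  co <- sim$cohort
  for (fam in unique(co$family)) {
    rows <- co[co$family == fam, , drop = FALSE]
    rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
    duo <- all(is.na(rows$pat_gt))
    pro <- rows$proband_id[1]
    mat <- paste0(fam, "_MAT"); pat <- paste0(fam, "_PAT")
    samples <- c(pro, mat, if (!duo) pat)
    hdr <- c(
      "##fileformat=VCFv4.2",
      paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"",
             "Consequence annotations. Format: ",
             paste(csq_field_spec()$order, collapse = "|"), "\">"),
      "##INFO=<ID=COHORT_AF,Number=1,Type=Float,Description=\"Cohort allele fraction\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
    body <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      csq <- csq_unpack(r$consequences)
      csq_str <- paste(vapply(seq_len(nrow(csq)), function(j) {
        paste(c(r$gene, csq$transcript[j], csq$term[j],
                .sim_fmt(csq$distance[j]),
                .sim_fmt(r$af_gnomad_exomes), .sim_fmt(r$af_gnomad_genomes),
                .sim_fmt(r$af_topmed), .sim_fmt(r$af_exac),
                .sim_fmt(r$af_1000g), .sim_fmt(r$cadd), .sim_fmt(r$revel),
                .sim_fmt(r$spliceai), .sim_fmt(r$clinvar),
                .sim_fmt(r$exomiser_rank), .sim_fmt(r$exomiser_score)),
              collapse = "|")
      }, character(1)), collapse = ",")
      info <- paste0("CSQ=", csq_str, ";COHORT_AF=",
                     .sim_fmt(r$cohort_af))
      member_field <- function(prefix) {
        gt <- r[[paste0(prefix, "_gt")]]
        if (is.na(gt)) return(NULL)
        paste0(.sim_gt_string(gt), ":",
               r[[paste0(prefix, "_ref_reads")]], ",",
               r[[paste0(prefix, "_alt_reads")]], ":",
               r[[paste0(prefix, "_gq")]])
      }
      fields <- c(member_field("pro"), member_field("mat"),
                  if (!duo) member_field("pat"))
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter_status,
              info, "GT:AD:GQ", fields), collapse = "\t")
    }, character(1))
    vcf_path <- file.path(out_dir, paste0(fam, ".vcf"))
    writeLines(c(hdr, body), vcf_path)
    paths[[paste0("vcf_", fam)]] <- vcf_path
  }

  ped <- sim$pedigree
  ped_out <- data.frame(
    family = ped$family, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(is.na(ped$sex), 0, ifelse(ped$sex == "M", 1, 2)),
    affected = ifelse(is.na(ped$affected), 0, ifelse(ped$affected, 2, 1)))
  paths$ped <- file.path(out_dir, "cohort.ped")
  write.table(ped_out, paths$ped, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  paths$truth <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")

  paths$panel <- file.path(out_dir, "panel.tsv")
  write.table(data.frame(gene = sim$genes$gene,
                         rating = ifelse(sim$genes$on_panel, "green",
                                         "red")),
              paths$panel, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$gencc <- file.path(out_dir, "gencc.tsv")
  write.table(data.frame(gene = sim$genes$gene,
                         classification = ifelse(sim$genes$in_gencc,
                                                 "Definitive", "Limited")),
              paths$gencc, sep = "\t", quote = FALSE, row.names = FALSE)

  exons <- do.call(rbind, lapply(seq_len(nrow(sim$genes)), function(i) {
    data.frame(chrom = sim$genes$contig[i],
               start = .sim_exon_starts - 1L,  # BED half-open
               end = .sim_exon_starts + .sim_exon_len - 1L,
               gene = sim$genes$gene[i])
  }))
  paths$exons <- file.path(out_dir, "exons.bed")
  write.table(exons, paths$exons, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
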