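het_variant <- function(consequence = "missense", ...) {
  variant_record("1", 100, "A", "G", gene = "G1",
                 consequence = consequence, pro_gt = "het", ...)
}

test_that("each exclusion criterion fires on its defining evidence", {
  # 1: lone het in a recessive gene with no second hit
  d <- evaluate_exclusions(het_variant(), "inherited_het_mat",
                           evidence_bundle(gene_disease_moi = "AR",
                                           second_hit_present = FALSE))
  expect_equal(d$verdict, "excluded")
  expect_equal(d$criterion, 1L)
  # ... but not when compound-het partnered
  d <- evaluate_exclusions(het_variant(), "comp_het_partner",
                           evidence_bundle(gene_disease_moi = "AR",
                                           second_hit_present = FALSE))
  expect_equal(d$verdict, "reportable")

  # 2: phenotype mismatch in a known disease gene
  d <- evaluate_exclusions(het_variant(), "de_novo",
                           evidence_bundle(gene_disease_moi = "AD",
                                           phenotype_match = FALSE))
  expect_equal(d$criterion, 2L)
  # ... ClinVar P/LP variants are exempt from criterion 2
  d <- evaluate_exclusions(het_variant(clinvar = "P"), "de_novo",
                           evidence_bundle(gene_disease_moi = "AD",
                                           phenotype_match = FALSE,
                                           igv_artefact = FALSE))
  expect_equal(d$verdict, "reportable")

  # 3: poorly expressed known disease gene
  d <- evaluate_exclusions(het_variant(), "de_novo",
                           evidence_bundle(gene_disease_moi = "AD",
                                           phenotype_match = TRUE,
                                           exon_expression_adequate = FALSE))
  expect_equal(d$criterion, 3L)

  # 4: novel gene outside the relevant pathway
  d <- evaluate_exclusions(het_variant(), "de_novo",
                           evidence_bundle(gene_disease_moi = "none-known",
                                           pathway_excluded = TRUE))
  expect_equal(d$criterion, 4L)

  # 5: predicted LoF curated as not LoF
  lof <- het_variant(consequence = "frameshift")
  d <- evaluate_exclusions(lof, "de_novo",
                           evidence_bundle(lof_curation = "not_LoF"))
  expect_equal(d$criterion, 5L)

  # 6: read-data artefact
  d <- evaluate_exclusions(het_variant(), "de_novo",
                           evidence_bundle(igv_artefact = TRUE))
  expect_equal(d$criterion, 6L)
})

test_that("a de novo frameshift in a well-supported novel gene is reportable", {
  hmgb1 <- variant_record("13", 30462666, "CT", "C", gene = "HMGB1",
                          consequence = "frameshift", pro_gt = "het")
  ev <- evidence_bundle(gene_disease_moi = "none-known",
                        tissue_expression_adequate = TRUE,
                        exon_expression_adequate = TRUE,
                        pathway_excluded = FALSE,
                        lof_curation = "LoF", igv_artefact = FALSE)
  d <- evaluate_exclusions(hmgb1, "de_novo", ev)
  expect_equal(d$verdict, "reportable")
  expect_equal(length(d$abstained), 0)
})

test_that("unknown evidence makes rules abstain, never fire", {
  d <- evaluate_exclusions(het_variant(consequence = "stop_gained"),
                           "inherited_het_mat", evidence_bundle())
  expect_equal(d$verdict, "reportable")
  expect_true(all(c("criterion_1", "criterion_2", "criterion_5",
                    "criterion_6") %in% d$abstained))
  # lowest firing index wins when several criteria fire
  ev <- evidence_bundle(gene_disease_moi = "AR",
                        second_hit_present = FALSE,
                        phenotype_match = FALSE, igv_artefact = TRUE)
  d <- evaluate_exclusions(het_variant(), "inherited_het_mat", ev)
  expect_equal(d$criterion, 1L)
})

test_that("resolving unknown evidence moves verdicts one way only", {
  set.seed(77)
  fields <- list(
    gene_disease_moi = c("AD", "AR", "XL", "none-known"),
    second_hit_present = c(TRUE, FALSE),
    phenotype_match = c(TRUE, FALSE),
    tissue_expression_adequate = c(TRUE, FALSE),
    exon_expression_adequate = c(TRUE, FALSE),
    pathway_excluded = c(TRUE, FALSE),
    lof_curation = c("LoF", "not_LoF", "likely_not_LoF"),
    igv_artefact = c(TRUE, FALSE))
  v <- het_variant(consequence = "stop_gained")
  for (rep in 1:40) {
    partial <- list()
    full <- list()
    for (f in names(fields)) {
      val <- sample(fields[[f]], 1)
      full[[f]] <- val
      if (stats::runif(1) < 0.5) partial[[f]] <- val
    }
    d1 <- evaluate_exclusions(v, "inherited_het_mat",
                              do.call(evidence_bundle, partial))
    d2 <- evaluate_exclusions(v, "inherited_het_mat",
                              do.call(evidence_bundle, full))
    if (d1$verdict == "excluded") expect_equal(d2$verdict, "excluded")
    if (d2$verdict == "excluded")
      expect_true(d2$criterion %in% 1:6)  # exhaustive index mapping
  }
})

test_that("candidate-set evaluation counts reportable verdicts per family", {
  sim <- generate_cohort(sim_config(seed = 19, n_families = 2,
                                    n_common_benign = 5))
  cs <- hippo_screen(sim$cohort)
  expect_gt(nrow(cs$variants), 0)
  # all evidence unknown: every candidate reportable, all rules abstain
  d <- evaluate_candidates(cs)
  expect_equal(nrow(d), nrow(cs$variants))
  expect_true(all(d$verdict == "reportable"))
  expect_true(all(d$evidence_missing))
  counts <- reportable_count(d)
  expect_equal(sum(counts$n_reportable), nrow(cs$variants))
  # all candidates artefactual: none reportable
  ev <- do.call(rbind, lapply(cs$variants$key, function(k) {
    data.frame(key = k, igv_artefact = TRUE)
  }))
  d2 <- evaluate_candidates(cs, ev)
  expect_true(all(d2$verdict == "excluded"))
  expect_true(all(d2$criterion == 6L))
  expect_equal(sum(reportable_count(d2)$n_reportable), 0)
})
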