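test_that("worked retention examples behave as published", {
  # de novo missense, gnomAD 0, CADD 26.7, ClinVar P: retained
  ppp1cb <- variant_record("2", 28776944, "C", "G", gene = "PPP1CB",
                           consequence = "missense", af = 0, cadd = 26.7,
                           revel = 0.438, clinvar = "P")
  r <- hippo_retain(ppp1cb, label = "de_novo")
  expect_true(r$retained)
  expect_equal(r$mode, "dominant")

  # common missense in dominant mode: removed by the AF rule
  common <- variant_record("1", 100, "A", "G", af = 0.01, cadd = 30)
  r <- hippo_retain(common, label = "de_novo")
  expect_false(r$retained)
  expect_true(any(grepl("^af:fail", r$trail)))

  # de novo missense CADD 12, no ClinVar record: removed by the CADD rule
  lowcadd <- variant_record("1", 200, "A", "G", af = 0, cadd = 12)
  r <- hippo_retain(lowcadd, label = "de_novo")
  expect_false(r$retained)
  expect_true("cadd:fail" %in% r$trail)

  # recessive comp-het partner, gnomAD 5.56e-4, CADD 23.5: retained
  ints1 <- variant_record("7", 1480876, "G", "C", gene = "INTS1",
                          consequence = "missense", af = 5.56e-4,
                          cadd = 23.5)
  r <- hippo_retain(ints1, label = "comp_het_partner")
  expect_true(r$retained)
  expect_equal(r$mode, "recessive")
  # an AF between the two ceilings passes recessive but not dominant
  mid <- variant_record("7", 999, "G", "C", af = 5e-3, cadd = 25)
  expect_true(hippo_retain(mid, label = "comp_het_partner")$retained)
  expect_false(hippo_retain(mid, label = "de_novo")$retained)
})

test_that("absent scores are skipped with a note, never treated as zero", {
  no_cadd <- variant_record("1", 10, "C", "T", af = 0)
  r <- hippo_retain(no_cadd, label = "de_novo")
  expect_true(r$retained)
  expect_true("cadd:absent" %in% r$trail)
  # a genuinely zero CADD fails instead
  zero_cadd <- variant_record("1", 10, "C", "T", af = 0, cadd = 0)
  r0 <- hippo_retain(zero_cadd, label = "de_novo")
  expect_false(r0$retained)
  expect_true("cadd:fail" %in% r0$trail)
})

test_that("strict boundaries fail: allele balance 0.2 and GQ 40", {
  v <- de_novo_record(pro_ref_reads = 8, pro_alt_reads = 2, pro_gq = 99)
  expect_false(hippo_retain(v, label = "de_novo")$retained)
  v2 <- de_novo_record(pro_gq = 40)
  expect_false(hippo_retain(v2, label = "de_novo")$retained)
  v3 <- de_novo_record(pro_gq = 41)
  expect_true(hippo_retain(v3, label = "de_novo")$retained)
})

test_that("splice handling: window, SpliceAI threshold and canonical LoF", {
  base <- function(...) variant_record("1", 100, "A", "G", af = 0,
                                       cadd = 20, ...)
  inside <- base(consequence = "intron", distance = 10, spliceai = 0.5)
  expect_true(hippo_retain(inside, label = "de_novo")$retained)
  weak <- base(consequence = "intron", distance = 10, spliceai = 0.1)
  expect_false(hippo_retain(weak, label = "de_novo")$retained)
  outside <- base(consequence = "intron", distance = 30, spliceai = 0.9)
  expect_false(hippo_retain(outside, label = "de_novo")$retained)
  canonical <- base(consequence = "splice_donor", distance = 1)
  r <- hippo_retain(canonical, label = "de_novo")
  expect_true(r$retained)
  expect_true("spliceai:absent_canonical_plof" %in% r$trail)
})

test_that("synonymous variants are excluded unless ClinVar rescues them", {
  syn <- variant_record("1", 50, "G", "A", consequence = "synonymous",
                        af = 0, cadd = 20, spliceai = 0.9)
  expect_false(hippo_retain(syn, label = "de_novo")$retained)
  syn_p <- variant_record("1", 50, "G", "A", consequence = "synonymous",
                          af = 0, cadd = 20, clinvar = "P")
  expect_true(hippo_retain(syn_p, label = "de_novo")$retained)
})

test_that("the ClinVar override dominates every other rule below its AF ceiling", {
  # inherited from an unaffected parent, poor quality, low CADD: retained
  abcc8 <- variant_record("11", 17413408, "G", "A", gene = "ABCC8",
                          consequence = "stop_gained", af = 1e-4,
                          cadd = 3, clinvar = "P",
                          pro_gt = "het", mat_gt = "hom_ref",
                          pat_gt = "het", pro_gq = 10,
                          pro_ref_reads = 9, pro_alt_reads = 1)
  expect_true(clinvar_override(abcc8))
  expect_true(hippo_retain(abcc8, label = "inherited_het_pat")$retained)
  # under arbitrary tighter thresholds too
  tight <- filter_config("hippo", cadd_min = 35, af_max_dominant = 1e-6,
                         af_max_recessive = 1e-6, gq_min = 99)
  expect_true(hippo_retain(abcc8, label = "inherited_het_pat",
                           cfg = tight)$retained)
  # above the safety ceiling the override does not fire
  common_p <- variant_record("1", 5, "A", "G", af = 0.2, clinvar = "P")
  expect_false(clinvar_override(common_p))
  # benign assertion with a high CADD is still removed
  benign <- variant_record("1", 6, "A", "G", af = 0, cadd = 30,
                           clinvar = "B")
  expect_false(clinvar_override(benign))
  expect_false(hippo_retain(benign, label = "de_novo")$retained)
  # VUS: override false, normal rules apply
  vus <- variant_record("1", 7, "A", "G", af = 0, cadd = 30,
                        clinvar = "VUS")
  expect_false(clinvar_override(vus))
  expect_true(hippo_retain(vus, label = "de_novo")$retained)
})

test_that("tightening thresholds never grows the retained set", {
  for (seed in c(3, 31)) {
    sim <- generate_cohort(sim_config(seed = seed, n_families = 2))
    base <- hippo_screen(sim$cohort)
    key <- function(cs) paste(cs$variants$family, cs$variants$key)
    tighter <- list(
      filter_config("hippo", cadd_min = 25),
      filter_config("hippo", af_max_dominant = 1e-5,
                    af_max_recessive = 1e-4),
      filter_config("hippo", gq_min = 70, allele_balance_min = 0.4)
    )
    for (cfg in tighter) {
      expect_true(all(key(hippo_screen(sim$cohort, cfg)) %in% key(base)))
    }
    # shrinking the gene list never grows the set either
    some_genes <- gene_list(sim$genes$gene[seq_len(5)])
    expect_true(all(key(restrict_to_genes(base, some_genes)) %in% key(base)))
  }
})

test_that("gene-list restriction is a subset with identity/empty extremes", {
  sim <- generate_cohort(sim_config(seed = 8, n_families = 1))
  cs <- hippo_screen(sim$cohort)
  expect_gt(nrow(cs$variants), 0)
  all_genes <- gene_list(sim$genes$gene)
  expect_equal(restrict_to_genes(cs, all_genes)$variants, cs$variants)
  none <- gene_list(character(0), allow_empty = TRUE)
  expect_equal(nrow(restrict_to_genes(cs, none)$variants), 0)
})

test_that("lone inherited heterozygotes need a partner or an override", {
  lone <- variant_record("1", 10, "A", "G", gene = "G1", af = 1e-4,
                         cadd = 30, pro_gt = "het", mat_gt = "het",
                         pat_gt = "hom_ref", pro_ref_reads = 10,
                         pro_alt_reads = 10, pro_gq = 99)
  cs <- hippo_screen(lone)
  expect_equal(nrow(cs$variants), 0)
  # a paternal partner in the same gene rescues both
  partner <- variant_record("1", 20, "C", "T", gene = "G1", af = 1e-4,
                            cadd = 30, pro_gt = "het", mat_gt = "hom_ref",
                            pat_gt = "het", pro_ref_reads = 10,
                            pro_alt_reads = 10, pro_gq = 99)
  cs2 <- hippo_screen(rbind(lone, partner))
  expect_equal(nrow(cs2$variants), 2)
  expect_setequal(cs2$variants$label, "comp_het_partner")
})
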