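panel_r29 <- gene_list(c("CHAMP1", "PPP1CB", "GENEX"), name = "R29",
                       provenance = "panelapp_green")

test_that("the pre-filter applies frequency, window, GQ and FILTER rules", {
  inh <- variant_record("1", 10, "A", "G", af = 5e-3, pro_gq = 60)
  expect_true(gms_prefilter(inh, label = "inherited_het_mat")$pass)
  # the same AF fails the dominant ceiling
  expect_false(gms_prefilter(inh, label = "de_novo")$core)

  # intronic at -15 bp: outside the 8 bp window though inside 20 bp
  intronic <- variant_record("1", 20, "A", "G", consequence = "intron",
                             distance = 15, af = 0, cadd = 25,
                             pro_gq = 60)
  expect_false(gms_prefilter(intronic, label = "de_novo")$core)
  expect_equal(nrow(consequence_hits(intronic$consequences, 20)), 1)

  lowgq <- variant_record("1", 30, "A", "G", af = 0, pro_gq = 30)
  pf <- gms_prefilter(lowgq, label = "de_novo")
  expect_false(pf$pass)
  expect_true(pf$core)
  nonpass <- variant_record("1", 40, "A", "G", af = 0, pro_gq = 60,
                            filter_status = "LowQual")
  expect_false(gms_prefilter(nonpass, label = "de_novo")$pass)
})

test_that("tier assignment follows the published definitions", {
  champ1 <- variant_record("13", 114325034, "C", "T", gene = "CHAMP1",
                           consequence = "stop_gained", af = 0, cadd = 35,
                           clinvar = "P")
  expect_equal(assign_tier(champ1, "de_novo", panel_r29)$tier, "TIER1")

  # off-panel inherited stop-gain without Exomiser support: untiered
  abcc8 <- variant_record("11", 17413408, "G", "A", gene = "ABCC8",
                          consequence = "stop_gained", af = 0)
  expect_equal(assign_tier(abcc8, "inherited_het_pat", panel_r29)$tier,
               "UNTIERED")

  # off-panel with a weak Exomiser rank: untiered
  pkd1l3 <- variant_record("16", 71951734, "T", "G", gene = "PKD1L3",
                           consequence = "missense", af = 5e-4,
                           exomiser_rank = 33L, exomiser_score = 0.7)
  expect_equal(assign_tier(pkd1l3, "inherited_het_mat", panel_r29)$tier,
               "UNTIERED")

  # off-panel, Exomiser rank 2 score 0.97: gene-agnostic channel
  ex <- variant_record("1", 5, "A", "G", gene = "OFFP",
                       consequence = "missense", af = 0,
                       exomiser_rank = 2L, exomiser_score = 0.97)
  expect_equal(assign_tier(ex, "inherited_het_mat", panel_r29)$tier,
               "GENE_AGNOSTIC_EXOMISER")

  # on-panel non-LoF inherited coding variant: TIER2
  t2 <- variant_record("1", 6, "A", "G", gene = "PPP1CB",
                       consequence = "missense", af = 1e-4)
  expect_equal(assign_tier(t2, "inherited_het_mat", panel_r29)$tier,
               "TIER2")

  # no panels: warning, only gene-agnostic possible
  expect_warning(ta <- assign_tier(champ1, "de_novo", list()),
                 "gene-agnostic")
  expect_equal(ta$tier, "GENE_AGNOSTIC_DENOVO")

  # synonymous never tiered, even with splice evidence
  syn <- variant_record("1", 7, "A", "G", gene = "CHAMP1",
                        consequence = "synonymous", af = 0,
                        spliceai = 0.95)
  expect_equal(assign_tier(syn, "de_novo", panel_r29)$tier, "UNTIERED")
})

test_that("non-PASS de novo coding variants survive via the gene-agnostic bypass", {
  dn <- de_novo_record(filter_status = "LowQual", gene = "OFFPANEL")
  cs <- gms_screen(dn, panel_r29)
  expect_equal(nrow(cs$variants), 1)
  expect_equal(cs$variants$tier, "GENE_AGNOSTIC_DENOVO")
  expect_match(cs$variants$trail, "bypass")
  # but a non-PASS inherited on-panel variant is lost
  inh <- variant_record("1", 9, "A", "G", gene = "CHAMP1", af = 1e-4,
                        pro_gt = "het", mat_gt = "het", pat_gt = "hom_ref",
                        pro_gq = 60, filter_status = "LowQual")
  expect_equal(nrow(gms_screen(inh, panel_r29)$variants), 0)
})

test_that("the Tier A CNV rule uses strict size and one shared base", {
  genes <- data.frame(chrom = "1", start = 20000, end = 25000)
  cnv <- data.frame(
    chrom = c("1", "1", "2"),
    start = c(21000, 5001, 1),
    end = c(25999, 20000, 50000))  # 5 kb on-gene; 15 kb sharing 1 bp; off
  expect_equal(tier_a_cnv(cnv, panel_genes = genes),
               c(FALSE, TRUE, FALSE))
  # curated-region overlap qualifies independently of gene overlap
  regions <- data.frame(chrom = "2", start = 10, end = 20)
  expect_true(tier_a_cnv(data.frame(chrom = "2", start = 1, end = 50000),
                         panel_genes = genes, curated_regions = regions))
})

test_that("every TIER1 variant is de novo or satisfies the TIER2 location rule", {
  sim <- generate_cohort(sim_config(seed = 13, n_families = 3))
  cs <- gms_screen(sim$cohort, sim$panel)
  t1 <- cs$variants[cs$variants$tier == "TIER1", ]
  for (i in seq_len(nrow(t1))) {
    locational <- nrow(consequence_hits(t1$consequences[i], 8)) > 0
    expect_true(locational || t1$label[i] == "de_novo")
  }
})

test_that("panel changes are monotone for tiered and gene-agnostic sets", {
  sim <- generate_cohort(sim_config(seed = 17, n_families = 3))
  key <- function(cs, tiers) {
    v <- cs$variants[cs$variants$tier %in% tiers, ]
    paste(v$family, v$key)
  }
  panel_tiers <- c("TIER1", "TIER2")
  ga_tiers <- c("GENE_AGNOSTIC_DENOVO", "GENE_AGNOSTIC_EXOMISER")
  full <- gms_screen(sim$cohort, sim$panel)
  half_genes <- sim$panel$symbols[seq_len(floor(length(sim$panel$symbols) / 2))]
  half <- gms_screen(sim$cohort,
                     gene_list(half_genes, provenance = "panelapp_green"))
  none <- suppressWarnings(gms_screen(sim$cohort, list()))
  # removing panel genes never adds tiered variants
  expect_true(all(key(half, panel_tiers) %in% key(full, panel_tiers)))
  expect_equal(length(key(none, panel_tiers)), 0)
  # adding a panel never removes gene-agnostic variants: every
  # gene-agnostic variant under the full panel is assessed without one
  expect_true(all(key(full, ga_tiers) %in% key(none, ga_tiers)))
})

test_that("off-panel non-de-novo causal variants are invisible to tiering but kept by the panel-agnostic screen", {
  # the central contrast: causal inherited pathogenic variants in genes
  # outside every applied panel, with no Exomiser support
  cfg <- sim_config(seed = 23, n_families = 3, n_common_benign = 10,
                    n_rare_benign = 5, n_de_novo = 0,
                    n_comp_het_pairs = 0, n_clinvar_p_inherited = 2,
                    on_panel_fraction = 0)
  sim <- generate_cohort(cfg)
  causal <- sim$truth[sim$truth$category == "clinvar_p_inherited", ]
  gms <- gms_screen(sim$cohort, sim$panel)
  hip <- hippo_screen(sim$cohort)
  gk <- paste(gms$variants$family, gms$variants$key)
  hk <- paste(hip$variants$family, hip$variants$key)
  ck <- paste(causal$family, causal$key)
  expect_equal(sum(ck %in% gk), 0)
  expect_equal(sum(ck %in% hk), length(ck))
  expect_gt(length(ck), 0)
})
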