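test_that("a single-variant configuration builds the announced record", {
  cfg <- sim_config(seed = 1, n_families = 1, n_common_benign = 0,
                    n_rare_benign = 0, n_de_novo = 1,
                    n_comp_het_pairs = 0, n_clinvar_p_inherited = 0,
                    on_panel_fraction = 1, nonpass_fraction = 0)
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 1)
  expect_equal(sim$truth$category, "de_novo_damaging")
  expect_equal(classify_trio(sim$cohort$pro_gt, sim$cohort$mat_gt,
                             sim$cohort$pat_gt), "de_novo")
  expect_true(sim$truth$expected_hippo)
  expect_equal(sim$truth$expected_gms, "TIER1")
})

test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(seed = 303, n_families = 2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the draws
  expect_false(identical(generate_cohort(sim_config(seed = 304,
                                                    n_families = 2))$cohort,
                         a$cohort))
})

test_that("an impossible configuration is rejected", {
  expect_error(sim_config(n_comp_het_pairs = 1,
                          missing_parent_families = 1),
               "both parents")
  expect_error(sim_config(n_common_benign = -1), "non-negative")
})

test_that("the panel-agnostic screen recovers exactly the expected-retain set", {
  for (seed in c(7, 29)) {
    sim <- generate_cohort(sim_config(seed = seed, n_families = 3))
    cs <- hippo_screen(sim$cohort)
    got <- paste(sim$truth$family, sim$truth$key) %in%
      paste(cs$variants$family, cs$variants$key)
    # 100% recall of expected-retain labels, including via VCF round trip
    expect_equal(got, sim$truth$expected_hippo)
    # 0% of common benign variants retained
    expect_equal(sum(got[sim$truth$category == "common_benign"]), 0)
    expect_gt(sum(sim$truth$expected_hippo), 0)
  }
})

test_that("the panel screen assigns exactly the expected tiers", {
  sim <- generate_cohort(sim_config(seed = 47, n_families = 3))
  cs <- gms_screen(sim$cohort, sim$panel)
  got <- cs$variants$tier[match(paste(sim$truth$family, sim$truth$key),
                                paste(cs$variants$family,
                                      cs$variants$key))]
  got[is.na(got)] <- "none"
  want <- sim$truth$expected_gms
  want[want %in% c("FAIL_PREFILTER", "UNTIERED")] <- "none"
  expect_equal(got, want)
})

test_that("off-panel inherited pathogenic variants separate the strategies", {
  # retained through the ClinVar override, untiered by the panel screen
  cfg <- sim_config(seed = 53, n_families = 2, n_common_benign = 5,
                    n_rare_benign = 2, n_de_novo = 0,
                    n_comp_het_pairs = 0, n_clinvar_p_inherited = 1,
                    on_panel_fraction = 0)
  sim <- generate_cohort(cfg)
  causal <- sim$truth[sim$truth$category == "clinvar_p_inherited", ]
  expect_equal(nrow(causal), 2)
  hip <- hippo_screen(sim$cohort)
  hit <- hip$variants[paste(hip$variants$family, hip$variants$key) %in%
                        paste(causal$family, causal$key), ]
  expect_equal(nrow(hit), 2)
  expect_true(all(hit$channel == "clinvar_override"))
  gms <- gms_screen(sim$cohort, sim$panel)
  expect_false(any(paste(causal$family, causal$key) %in%
                     paste(gms$variants$family, gms$variants$key)))
})

test_that("generated files read back into the generated cohort", {
  d <- tempfile()
  sim <- generate_cohort(sim_config(seed = 61, n_families = 1,
                                    n_common_benign = 6,
                                    n_rare_benign = 3), out_dir = d)
  ped <- read_pedigree(file.path(d, "cohort.ped"))
  co <- read_trio_vcf(file.path(d, "FAM01.vcf"), ped)
  expect_equal(nrow(co), nrow(sim$cohort))
  ord <- function(x) {
    x <- x[order(x$chrom, x$pos, x$alt), ]
    rownames(x) <- NULL
    x
  }
  a <- ord(sim$cohort); b <- ord(co)
  expect_equal(a$pro_gt, b$pro_gt)
  expect_equal(a$clinvar, b$clinvar)
  expect_equal(a$cadd, b$cadd, tolerance = 1e-4)  # VCF prints 6 sig figs
  expect_equal(a$cohort_af, b$cohort_af, tolerance = 1e-4)
  expect_equal(is.na(a$cadd), is.na(b$cadd))
  # gene lists read back with their classification filters applied
  panel <- read_gene_list(file.path(d, "panel.tsv"), "panelapp_green")
  expect_setequal(panel$symbols, sim$panel$symbols)
  gencc <- read_gene_list(file.path(d, "gencc.tsv"),
                          "gencc_strong_definitive")
  expect_setequal(gencc$symbols, sim$gencc$symbols)
})
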