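---
title: "Trio variant triage: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant triage: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippotrio)
```

## The problem

Clinical genome analysis for rare disease must reduce millions of called
variants to a handful a laboratory can manually assess. Two filtering
philosophies compete. A *panel-based* workflow — the one used by the NHS
Genome Medicine Service (GMS) — restricts assessment to "green" genes on
virtual panels selected by the referring clinician, plus a small
gene-agnostic channel (de novo coding variants and top-ranked Exomiser
hits). A *panel-agnostic* workflow instead keeps any variant with high
pathogenic potential, wherever it falls, using population allele
frequency, in-silico scores (CADD, SpliceAI), ClinVar assertions and trio
segregation. The package implements both workflows over the same
normalised trio records so their diagnostic efficiency — hits per variant
a human must assess — can be compared directly on identical inputs.

## Record model

`read_trio_vcf()` normalises an annotated multi-sample VCF against a PED
pedigree into one row per bi-allelic variant per analysis trio.
Multi-allelic sites are split with per-allele depths; a quad pedigree
decomposes into one trio per affected child with the parents duplicated,
mirroring clinical practice. Two annotation dialects are supported: a
packed VEP-CSQ-style INFO field whose layout is declared with
`csq_field_spec()`, and a sidecar TSV keyed by chrom/pos/ref/alt
(`attach_annotations()`). All coordinates are 1-based VCF convention
throughout; there is no internal 0-based layer.

A deliberate invariant: an *absent* annotation is `NA`, never 0. A
missing CADD score means "no evidence", and the CADD rule abstains with a
trail note; a CADD of 0 is evidence and fails the threshold. The single
exception, following the filtering convention the thresholds come from,
is population allele frequency, where absence from every reference
population is itself informative and counts as 0 (a novel variant).

## Inheritance classification

`classify_trio()` labels each variant's segregation with a fixed
precedence: `de_novo` (proband carries the alternate, both parents
present and homozygous reference) then `hemizygous` (X non-PAR, male
proband, carrier mother, non-carrier father; PAR boundaries default to
GRCh38 and are configurable) then `hom_recessive` (proband homozygous
alternate, every present parent carrying at most one alternate allele)
then the inherited heterozygous labels, else `uninformative`. A missing
parental genotype never produces a de novo call — the record is kept but
routed through the dominant search without a de novo claim, a
conservative default for joint-called trios.

`find_compound_hets()` pairs heterozygous variants in one gene that were
transmitted from different parents (in trans by transmission). A de novo
heterozygote may pair with an inherited one — cis configuration cannot be
proven without read-backed phasing, which is out of scope — but two de
novo variants, or two variants from the same parent, never pair. The
classifier is tested against an exhaustive truth-table enumeration over
all genotype combinations, and the pairing rule against brute force over
all 2-subsets.

How the recessive search should treat hemizygous variants is not pinned
down by the published criteria; the package classifies them as above,
routes them through the recessive thresholds, and carries the label in
the output so downstream users can see the assumption.

## The panel-agnostic retention rules

`hippo_retain()` keeps a variant when all of the following hold, each
with a strict inequality exactly as the criteria are printed:

| rule | dominant search | recessive search |
|---|---|---|
| max population AF (gnomAD exomes/genomes, TOPMED, ExAC, 1000G) | < 0.001 | < 0.05 |
| cohort AF | < 0.01 | < 0.01 |
| consequence | coding ± 20 bp, any transcript, never synonymous | same |
| SpliceAI (splicing variants only) | > 0.2 | > 0.2 |
| CADD (when present) | > 15 | > 15 |
| ClinVar | not B/LB | not B/LB |
| proband allele balance (het calls) | > 0.2 | > 0.2 |
| proband genotype quality | > 40 | > 40 |
| FILTER | all variants | all variants |

"On any transcript" means one qualifying transcript consequence
suffices, and the qualifying transcript is recorded in the rule trail.
For variants qualifying only through splice relevance (canonical sites,
splice regions, intronic positions inside the window), SpliceAI > 0.2 is
required — except canonical donor/acceptor disruptions with no SpliceAI
score, which are retained as predicted loss of function. Synonymous
variants are excluded with no SpliceAI rescue, because the printed
criteria exclude them without a rescue clause; a ClinVar
pathogenic assertion is the only path back in. REVEL is carried as an
annotation but never filtered on (the criteria list no REVEL threshold).

A ClinVar Pathogenic/Likely-pathogenic assertion overrides everything —
inheritance, scores, quality, presence in unaffected parents — below a
safety ceiling of population AF < 0.05. The published criteria do not
state whether their override carried a frequency ceiling; one is imposed
here as a guard against common P-asserted alleles, and is configurable
(`override_af_ceiling`). Similarly, whether the genotype-quality rule
applied to parents as well as the proband is unstated; the default is
proband-only with a `gq_all_members` switch.

`hippo_screen()` wires the rules into the two searches: de novo (and
parent-missing) variants are judged under the dominant frequency
ceiling; homozygous, hemizygous and inherited heterozygous variants
under the recessive one, with lone inherited heterozygotes surviving
only through compound-het pairing or the override. Every retained
variant carries a non-empty rule trail naming the rules it passed,
skipped or was rescued by. `restrict_to_genes()` optionally intersects
the candidate set with a disease-gene list (e.g. GenCC
strong/definitive) after retention.

## The panel-based tiering rules

`gms_prefilter()` applies the corresponding genome workflow: max
population AF < 0.001 (dominant) / < 0.01 (recessive), coding ± 8 bp
non-synonymous on any transcript, genotype quality > 30, PASS calls
only — with no cohort-AF, CADD, SpliceAI or ClinVar rules. Cohort AF has
no threshold in that workflow, so none is applied. `assign_tier()` then
assigns TIER1 (predicted LoF or de novo in a green panel gene), TIER2
(other qualifying coding variant in a green panel gene),
GENE_AGNOSTIC_DENOVO (de novo coding, any gene) or
GENE_AGNOSTIC_EXOMISER (Exomiser rank ≤ 3 and score ≥ 0.95), reporting
one tier per variant at precedence TIER1 > TIER2 > gene-agnostic. The
gene-agnostic channel is not filtered on quality: it bypasses the GQ and
FILTER rules but not the frequency/consequence rules. Synonymous
variants are never tiered, even with splice evidence, matching the
stated workflow. Predicted LoF defaults to stop-gained, frameshift,
canonical splice donor/acceptor, start-lost and stop-lost
(configurable). The ± 8 bp measurement convention is not stated in the
source workflow; genomic distance to the nearest annotated exon edge is
used, and the same convention feeds both strategies so the 8 vs 20 bp
contrast is clean. `tier_a_cnv()` implements the copy-number rule: size
strictly over 10 kb and at least one shared base with a curated
pathogenic region or a green-gene interval.

## Reporting exclusion criteria

`evaluate_exclusions()` encodes the six post-filtering reporting rules
as a declarative rule set over an `evidence_bundle()`: (1) lone
heterozygote in a known recessive gene without a second hit, (2)
phenotype mismatch in a known disease gene unless ClinVar P/LP, (3)
inadequate tissue or exon-level expression in a known gene, (4) novel
gene with inadequate expression or explicit pathway exclusion, (5)
predicted LoF manually curated as not LoF, (6) artefact on read
visualisation. Inputs that require human judgement (phenotype match, LoF
curation, read review) are consumed as flags — the engine records
curation, it never replicates it. An unknown field makes its rule
*abstain*, listed in the output, rather than default to false: adding
evidence can therefore only move a verdict from reportable to excluded,
never back, and that monotonicity is property-tested. Expression
adequacy is a supplied flag upstream of the engine; where users derive
it from reference expression data, the documented defaults are TPM ≥ 1
and pext ≥ 0.1 — the source criteria name the resources but no cut-offs,
so these are package assumptions, stated as such.

## Comparison statistics

`rate_per_assessed()` is the efficiency metric: hits per variant a
laboratory must assess, as a percentage. `compare_strategies()` restricts
to families comparable across both arms (dropping, with a warning,
families lacking a result in either arm or flagged as structurally
different between arms), sums assessed/diagnostic/reportable counts,
computes the six rates, intersects the reported sets by
chrom:pos:ref:alt identity, and runs paired Wilcoxon signed-rank tests
on the per-family assessed counts. CNVs are excluded from all counts.
"Diagnostic" is a consumed flag (a variant clinically accepted as
explaining, or partly explaining, the phenotype), never inferred from
scores.

`wilcoxon_signed_rank()` defaults to the normal approximation with
continuity correction and tie-corrected variance — the convention that
reproduces the published p-values on the packaged per-family counts
(0.022 for the disease-gene-restricted comparison, 0.35 for the
all-gene one); the same source prints 0.035 for the latter in one place,
which does not reproduce from its own table and is treated as a
typographical slip. An exact method (full enumeration of sign
assignments over mid-ranks, zeros dropped) is provided and
cross-checked against both `stats::wilcox.test(exact = TRUE)` on untied
data and a literal enumeration oracle; on the seven packaged pairs the
exact method gives a different value than the printed one, which is why
the normal approximation is the default. The packaged per-family
panel-agnostic counts sum to 171 across nine families while the source
prose reports 174; the per-family column is used for every derived
quantity here, and all printed denominators (109, 59, 63, 41, 15) and
rates reproduce from it.

## The synthetic cohort generator

`generate_cohort()` exists so every stage is testable end to end without
any external data. Each gene occupies its own synthetic contig with five
declared 200 bp exons, so exon distances are computable and no reference
genome is needed. Per family it draws: common benign variants (AF
0.01–0.5, CADD 0–10), rare benign variants (AF < 0.001, CADD 0–10), de
novo damaging variants (AF 0, CADD 20–45, Exomiser-annotated),
compound-het pairs (AF < 0.01, CADD 16–40, one maternal and one
paternal) and inherited ClinVar-pathogenic stop-gains. Defaults are nine
trio families with 40/15/2/1(pair)/1 variants per category — the cohort
scale of a small rare-disease trio study, and enough benign background
that a screen keeping everything would be obvious. Depths are Poisson
(mean 30) with binomial allele draws; genotype quality is uniform
(30–99 benign, 60–99 damaging); 5% of records are non-PASS.

Every variant carries a truth label with the expected verdict of each
screen, derived declaratively from the drawn values (so a damaging
variant that happens to draw a failing allele balance is *expected* to
be dropped, and the tests check exact agreement in both directions, not
just recall of a favourable subset). The seed fully determines the
output byte for byte. What the generator does not emulate — linkage,
realistic site-frequency spectra, mosaicism, read-level artefacts,
multi-allelic sites, X-chromosome inheritance — bounds what the passing
tests show: they validate the decision logic and its plumbing on clean
annotations, not robustness to annotation noise in real VCFs.

## Numerical and degenerate-input choices

Threshold comparisons are strict wherever the source prints a strict
symbol: allele balance exactly 0.2, GQ exactly 40 (or 30), CADD exactly
15 and a 10,000 bp CNV all fail. A heterozygous call with zero total
depth yields an undefined allele balance, which fails the balance rule.
A signed-rank test with every difference zero returns p = 1 with a
warning; fewer than three non-zero differences warns. Exact enumeration
is capped at 20 non-zero differences (2^20 sign vectors). An empty
candidate set writes a header-only TSV; the packaged study tables are
checksummed so silent edits of the transcription are fatal. Test and
example problem sizes (two to three synthetic families, a handful of
seeds) are chosen to exercise every code path while keeping the whole
suite in the tens of seconds.

## Command line

The installed `exec/hippotrio` script exposes `simulate`,
`filter-hippo`, `tier-gms`, `exclude` and `compare`. Thresholds are
never hard-coded at call sites: both strategies' printed defaults ship
as YAML under `inst/extdata/config/` and flow through `filter_config()`,
which logs any override. Every run writes a JSON manifest (version,
config hash, input checksums, per-stage counts, which are non-increasing
along each filter chain); identical inputs reproduce identical outputs.
The annotation transcript set (RefSeq vs Ensembl) is whatever the input
VCF was annotated with — the configuration declares the field layout and
the package takes no position on which set is correct.
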