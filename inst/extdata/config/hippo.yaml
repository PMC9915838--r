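# Panel-agnostic retention thresholds (published defaults).
strategy: hippo
af_max_dominant: 0.001     # max population AF, de novo/dominant search
af_max_recessive: 0.05     # max population AF, recessive search
cohort_af_max: 0.01        # within-cohort allele fraction ceiling
coding_window_bp: 20       # coding +/- 20 bp, any transcript
spliceai_min: 0.2          # SpliceAI, splicing variants only (strict >)
cadd_min: 15               # CADD, all variants (strict >)
allele_balance_min: 0.2    # proband het calls (strict >)
gq_min: 40                 # proband genotype quality (strict >)
require_pass: false        # all variants considered, not only PASS
override_af_ceiling: 0.05  # safety ceiling on the ClinVar P/LP override
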