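# Panel-based tiering thresholds (published defaults).
strategy: gms
af_max_dominant: 0.001     # max population AF, de novo/dominant search
af_max_recessive: 0.01     # max population AF, recessive search
coding_window_bp: 8        # coding +/- 8 bp, any transcript
gq_min: 30                 # genotype quality (strict >)
require_pass: true         # PASS calls only (gene-agnostic channel exempt)
exomiser_score_min: 0.95   # gene-agnostic Exomiser channel
exomiser_rank_max: 3
cnv_min_size_bp: 10000     # Tier A CNV size (strict >)
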