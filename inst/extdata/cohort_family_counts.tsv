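# Per-family variant-assessment counts from a published nine-family cohort
# in which each family underwent both panel-agnostic exome triage and
# panel-based clinical genome analysis. gms_passing is the number of
# short variants (tiered + gene-agnostic) returned for assessment by the
# clinical laboratory; NA where no genome report exists. paired marks
# families comparable across both arms (FAM_4 was sequenced with a
# different family structure in the two arms; FAM_7 has no genome report).
family	proband	hippo_variants	hippo_gencc_variants	gms_passing	gms_report	paired	note
FAM_1	1	8	3	9	yes	TRUE	.
FAM_2	4	4	4	5	yes	TRUE	.
FAM_3	7	4	2	7	yes	TRUE	.
FAM_4	10;13	68	23	14	yes	FALSE	maternal sample absent from the exome arm; genome arm sequenced as two trios
FAM_5	14	8	1	5	yes	TRUE	.
FAM_6	17	2	1	6	yes	TRUE	.
FAM_7	20	62	21	NA	no	FALSE	genome report pending
FAM_8	23	10	1	7	yes	TRUE	.
FAM_9	26	5	3	24	yes	TRUE	.
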