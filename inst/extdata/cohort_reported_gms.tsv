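# The 5 variants included on the clinical genome reports of the same
# cohort (4 patients): two pathogenic diagnoses, one VUS, and a
# compound-heterozygous pathogenic + VUS pair not felt to explain the
# phenotype. Variant keys use the exome-table coordinates where the two
# printed tables disagree on a coordinate for the same HGVS change.
variant	gene	class	diagnostic	family
13:30462666:CT:C	HMGB1	VUS	FALSE	FAM_1
2:28776944:C:G	PPP1CB	P	TRUE	FAM_3
13:114325034:C:T	CHAMP1	P	TRUE	FAM_6
1:243341070:TG:T	SDCCAG8	P	FALSE	FAM_9
1:243378799:A:G	SDCCAG8	VUS	FALSE	FAM_9
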