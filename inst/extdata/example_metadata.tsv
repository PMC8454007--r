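sample_id	subject_id	role	timepoint_days	pre_fmt	donor_link	response	segment
D1	D1	donor	0	FALSE	NA	none	NA
R1_t0	R1	recipient	0	TRUE	D1	R	NA
R1_t7	R1	recipient	7	FALSE	D1	R	NA
R1_t31	R1	recipient	31	FALSE	D1	R	NA
R1_t65	R1	recipient	65	FALSE	D1	R	NA
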