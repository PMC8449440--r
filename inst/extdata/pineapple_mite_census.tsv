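family	focal	n_elements	n_intact	length_range_bp	total_length_bp	pct_genome	tsd	tir_range_bp
Ac-mMITE-1	TRUE	28426	9889	510-570	10279806	2.69	(TA)n	140-180
Ac-mMITE-2	TRUE	24588	12105	210-270	4478432	1.17	(TA)n	40-70
other-MITEs	FALSE	159337	29851	70-1300	35452553	9.28	2-10bp	8-400
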