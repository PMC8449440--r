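quantity	value
full_length_total	21994
clustered_elements	10137
clustered_mt	9573
clusters_total	4024
mt_total	15361
ml_total	1435
mt_present	5736
ml_present	851
clusters_present	1123
clusters_absent	605
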