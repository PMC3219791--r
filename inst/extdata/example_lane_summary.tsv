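sample	total_reads	purity_filtered	repeat_masked	unmatched	uniquely_mapped	mapped_to_genes
shoot_NaOH	87.9	70.7	5.4	4.4	60.7	55.59
root_NaOH	90.2	68	4.9	4.4	58.6	51.78
shoot_ABA	80.5	64.5	4.6	2.3	57.5	52.31
root_ABA	84.2	65.3	5.0	3.5	56.5	50.32
shoot_H2O	88.7	66.3	4.9	6.3	54.7	49.59
root_H2O	88.8	67.7	4.7	6.6	56.3	49.74
shoot_PEG	87	67.2	5.3	1.2	59.7	53.89
root_PEG	82.2	66.2	4.8	2.4	58.9	52.38
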