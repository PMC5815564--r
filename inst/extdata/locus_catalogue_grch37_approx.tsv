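locus	chrom	start	end	direction
3q26.2	chr3	168400000	171100000	gain
3q21.3	chr3	127800000	129300000	gain
8q_arm	chr8	46500000	146000000	gain
8p_arm	chr8	1	43800000	loss
13q_arm	chr13	19500000	115000000	loss
16q_arm	chr16	38600000	90000000	loss
10q23.31	chr10	89500000	90000000	loss
17p13.1	chr17	7400000	7700000	loss
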