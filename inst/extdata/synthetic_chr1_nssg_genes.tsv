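fst	n_genes	n_outlier_genes
1.000	76	76
0.970	68	68
0.925	19	19
0.850	34	10
0.750	34	0
0.650	21	0
0.550	27	0
0.450	25	0
0.300	9	0
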