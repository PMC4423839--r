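dataset_id	cancer_type	n_patients	n_pairs_human_vs_xeno	n_pairs_xeno_vs_xeno	max_passage
GSE6465	hepatocellular_carcinoma	7	7	0	?
GSE55828	hepatocellular_carcinoma	9	9	0	3
GSE35144	colorectal_cancer	14	19	5	14
GSE46106	breast_cancer	1	0	4	15
GSE45153	head_and_neck_squamous_cell_carcinoma	5	4	3	10
GSE28996	adenoid_cystic_carcinoma	5	5	0	16
GSE46385	pancreatic_ductal_adenocarcinoma	5	1	10	12
GSE57491	b_cell_precursor_acute_lymphoblastic_leukaemia	9	9	0	?
GSE15240	small_cell_lung_cancer	3	2	1	2
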