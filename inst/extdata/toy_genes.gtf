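1	toy	gene	100	500	.	-	.	gene_id "G1"; gene_name "ALPHA"; gene_biotype "protein_coding";
1	toy	gene	1000	2000	.	+	.	gene_id "G2"; gene_name "BETA"; gene_biotype "pseudogene";
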