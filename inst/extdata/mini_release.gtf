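#!annotrack demo release (synthetic)
1	demo	gene	1000	5000	.	+	.	gene_id "DEMOG001.2"; gene_name "ALPHA"; gene_biotype "protein_coding";
1	demo	transcript	1000	5000	.	+	.	gene_id "DEMOG001.2"; transcript_id "DEMOT001.1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";
1	demo	exon	1000	1499	.	+	.	gene_id "DEMOG001.2"; transcript_id "DEMOT001.1"; exon_number "1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";
1	demo	exon	3000	5000	.	+	.	gene_id "DEMOG001.2"; transcript_id "DEMOT001.1"; exon_number "2"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";
1	demo	transcript	1000	3500	.	+	.	gene_id "DEMOG001.2"; transcript_id "DEMOT002.1"; gene_biotype "protein_coding"; transcript_biotype "retained_intron";
1	demo	exon	1000	3500	.	+	.	gene_id "DEMOG001.2"; transcript_id "DEMOT002.1"; exon_number "1"; gene_biotype "protein_coding"; transcript_biotype "retained_intron";
2	demo	gene	200	900	.	-	.	gene_id "DEMOG002.1"; gene_name "BETA"; gene_biotype "lincRNA";
2	demo	transcript	200	900	.	-	.	gene_id "DEMOG002.1"; transcript_id "DEMOT003.3"; gene_biotype "lincRNA"; transcript_biotype "lincRNA";
2	demo	exon	200	449	.	-	.	gene_id "DEMOG002.1"; transcript_id "DEMOT003.3"; exon_number "1"; gene_biotype "lincRNA"; transcript_biotype "lincRNA";
2	demo	exon	600	900	.	-	.	gene_id "DEMOG002.1"; transcript_id "DEMOT003.3"; exon_number "2"; gene_biotype "lincRNA"; transcript_biotype "lincRNA";
HSCHR1_1_CTG3	demo	gene	100	400	.	+	.	gene_id "DEMOG900.1"; gene_name "ALTC"; gene_biotype "protein_coding";
HSCHR1_1_CTG3	demo	transcript	100	400	.	+	.	gene_id "DEMOG900.1"; transcript_id "DEMOT900.1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";
HSCHR1_1_CTG3	demo	exon	100	400	.	+	.	gene_id "DEMOG900.1"; transcript_id "DEMOT900.1"; exon_number "1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";
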