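#tax_id	GeneID	status	RNA_nucleotide_accession.version	RNA_nucleotide_gi	protein_accession.version	protein_gi	genomic_nucleotide_accession.version	genomic_nucleotide_gi	start_position_on_the_genomic_accession	end_position_on_the_genomic_accession	orientation	assembly	mature_peptide_accession.version	mature_peptide_gi	Symbol
9606	1001	VALIDATED	NM_900001.1	-	NP_900001.1	-	-	-	-	-	-	-	-	-	GENE1001
9606	1001	VALIDATED	NM_900002.1	-	NP_900002.1	-	-	-	-	-	-	-	-	-	GENE1001
9606	1002	VALIDATED	NM_900003.1	-	NP_900003.1	-	-	-	-	-	-	-	-	-	GENE1002
9606	1003	VALIDATED	NM_900004.1	-	NP_900004.1	-	-	-	-	-	-	-	-	-	GENE1003
9606	1004	VALIDATED	NM_900005.1	-	NP_900005.1	-	-	-	-	-	-	-	-	-	GENE1004
9606	1001	VALIDATED	-	-	-	-	-	-	-	-	-	-	-	-	GENE1001
10090	555	VALIDATED	NM_555555.1	-	NP_555555.1	-	-	-	-	-	-	-	-	-	Mock1
9606	9999	VALIDATED	NM_999999.1	-	NP_999999.1	-	-	-	-	-	-	-	-	-	GENE9999
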