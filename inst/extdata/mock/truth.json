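{"terms":["GO:0008152","GO:1000001","GO:1000002","GO:1000003","GO:1000004","GO:1000005"],"genes":[1001,1002,1003,1004],"transcripts":["NM_900001","NM_900002","NM_900003","NM_900004","NM_900005"],"proteins":["NP_900001","NP_900002","NP_900003","NP_900004","NP_900005"],"ecs":["1.1.1.1","1.1.1.2","1.1.1.3"],"reactions":["R00002","R00003"],"compounds":["C00001","C00002","C00003","C00004","C00005","C00006"],"edges":{"gene_go":[{"gene_id":1001,"term_id":"GO:1000005"},{"gene_id":1002,"term_id":"GO:1000002"},{"gene_id":1002,"term_id":"GO:1000004"},{"gene_id":1003,"term_id":"GO:1000001"},{"gene_id":1003,"term_id":"GO:1000003"},{"gene_id":1004,"term_id":"GO:1000003"}],"gene_transcript":[{"gene_id":1001,"rna_accession":"NM_900001"},{"gene_id":1001,"rna_accession":"NM_900002"},{"gene_id":1002,"rna_accession":"NM_900003"},{"gene_id":1003,"rna_accession":"NM_900004"},{"gene_id":1004,"rna_accession":"NM_900005"}],"transcript_protein":[{"rna_accession":"NM_900001","protein_accession":"NP_900001"},{"rna_accession":"NM_900002","protein_accession":"NP_900002"},{"rna_accession":"NM_900003","protein_accession":"NP_900003"},{"rna_accession":"NM_900004","protein_accession":"NP_900004"},{"rna_accession":"NM_900005","protein_accession":"NP_900005"}],"protein_ec":[{"protein_accession":"NP_900002","ec_number":"1.1.1.3"},{"protein_accession":"NP_900004","ec_number":"1.1.1.1"},{"protein_accession":"NP_900004","ec_number":"1.1.1.2"},{"protein_accession":"NP_900005","ec_number":"1.1.1.2"}],"ec_reaction":[{"ec_number":"1.1.1.1","reaction_id":"R00002"},{"ec_number":"1.1.1.2","reaction_id":"R00002"},{"ec_number":"1.1.1.2","reaction_id":"R00003"},{"ec_number":"1.1.1.3","reaction_id":"R00002"}],"reaction_compound":[{"reaction_id":"R00002","compound_id":"C00001"},{"reaction_id":"R00002","compound_id":"C00004"},{"reaction_id":"R00002","compound_id":"C00005"},{"reaction_id":"R00003","compound_id":"C00002"},{"reaction_id":"R00003","compound_id":"C00003"},{"reaction_id":"R00003","compound_id":"C00006"}]},"term_to_compounds":{"GO:1000001":["C00001","C00002","C00003","C00004","C00005","C00006"],"GO:1000003":["C00001","C00002","C00003","C00004","C00005","C00006"],"GO:1000005":["C00001","C00004","C00005"]},"term_to_genes":{"GO:1000001":[1003],"GO:1000002":[1002],"GO:1000003":[1003,1004],"GO:1000004":[1002],"GO:1000005":[1001]},"background_n":6}
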