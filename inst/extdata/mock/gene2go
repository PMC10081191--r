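#tax_id	GeneID	GO_ID	Evidence	Qualifier	GO_term	PubMed	Category
9606	1001	GO:1000005	IEA	-	mock term	-	Process
9606	1002	GO:1000002	IEA	-	mock term	-	Process
9606	1002	GO:1000004	IEA	-	mock term	-	Process
9606	1003	GO:1000001	IEA	-	mock term	-	Process
9606	1003	GO:1000003	IEA	-	mock term	-	Process
9606	1004	GO:1000003	IEA	-	mock term	-	Process
10090	555	GO:1000001	IEA	-	mock term	-	Process
9606	1001	GO:1000001	IEA	NOT	mock term	-	Process
9606	9999	GO:0990001	IEA	-	mock term	-	Process
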