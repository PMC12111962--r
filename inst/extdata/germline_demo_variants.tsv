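patient_id	gene	clinical_significance	af_gnomad	af_1000g	cadd_phred	polyphen	sift	review_pass
P001	TP53	Pathogenic	0.0001	NA	35	Probably damaging	Deleterious	TRUE
P002	BRCA2	Likely pathogenic	0.0005	0.0002	28	Possibly damaging	Deleterious	TRUE
P003	SERPINA1	Pathogenic	0.05	0.001	30	Probably damaging	Deleterious	TRUE
P004	CDKN2A	Pathogenic	0.2	0.1	25	Probably damaging	Deleterious	TRUE
P005	NOTCH1	Pathogenic	0.0001	NA	32	Probably damaging	Deleterious	TRUE
P006	RAD50	Pathogenic	0.0002	NA	27	Probably damaging	Deleterious	FALSE
P007	MUTYH	Uncertain significance	0.001	NA	21	Possibly damaging	Tolerated	TRUE
P008	ATM	Uncertain significance	0.002	0.001	12	Probably damaging	Deleterious	TRUE
P009	CHEK2	Uncertain significance	0.001	NA	25	Benign	Tolerated	TRUE
P010	PALB2	Uncertain significance	0.0005	NA	NA	NA	NA	TRUE
P011	MLH1	other	0.0001	NA	30	Probably damaging	Deleterious	TRUE
P012	MSH2	Conflicting interpretations	0.0001	NA	30	Probably damaging	Deleterious	TRUE
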