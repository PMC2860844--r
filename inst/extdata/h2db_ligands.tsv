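pdb_code	description	sequence	length	distinct_flag
1FG2	LCMV Peptidic Epitope (gp33)	LAVYNFATC	9	TRUE
1JPF	LCMV Peptidic Epitope (gp276)	SGVENPGGYCL	11	TRUE
1JPG	LCMV Peptidic Epitope (np396)	FQPQNGQFI	9	TRUE
1INQ	MHC Class I H13a minor histocompatibility peptide	SSVVGVWYL	9	TRUE
1JUF	Minor Histocompatibility Antigen peptide (H13b) P4(Val/Ile)	SSVIGVWYL	9	TRUE
1N3N	Mycobacterial hsp60 epitope	SALQNAASIA	10	TRUE
1QLF	Sendai NP 324-332 (gly327 replaced by o-glcnac serine)	FAPSNYPAL	9	TRUE
1S7U/2F74/1FFN/1N5A	LCMV-derived immunodominant peptide (gp33)	KAVYNFATM	9	TRUE
1S7V	LCMV-derived (gp33) index peptide - escape variants	KAVYNLATM	9	TRUE
1S7W	LCMV-derived (gp33) index peptide - escape variants	KALYNFATM	9	TRUE
1S7X	LCMV-derived (gp33) index peptide - escape variants	KAVFNFATM	9	TRUE
1FFO	Gp33 synthetic peptide with substitution K1A/C9M	AAVYNFATM	9	TRUE
1FFP	Gp33 synthetic peptide with substitution K1S/C9M	SAVYNFATM	9	TRUE
1WBX	Peptide from Influenza A (pr8) HA 468-477	SQLKNNAKEI	10	TRUE
1WBY/1YN6	Peptide from Influenza A (pr8) PA 224-233	SSLENFRAYV	10	TRUE
1YN7	Mutated peptide (R7A) from RNA polymerase subunit P2	SSLENFAAYV	10	TRUE
1ZHB	9-mer peptide from Dopamine beta-monooxygenase	KALYNYAPI	9	TRUE
1BZ9	Synthetic Peptide (P1027)	FAPGVFPYM	9	TRUE
1CE6	Sendai Virus Nucleoprotein Peptide (NP 324-332)	FAPGNYPAL	9	TRUE
2VE6	Altered peptide of Sendai virus (photocleavable peptide)	FAPGNYPAL	9	TRUE
2CII	Sendai virus nucleoprotein epitope	FAPGNYPAL	9	FALSE
2ZOK	9-meric peptide from Spike glycoprotein	ASLWNGPHL	9	TRUE
2ZOL	9-meric peptide from Spike glycoprotein - Mutation: W4S	ASLSNGPHL	9	TRUE
1HOC	Influenza virus peptide NP 366-374	ASNENMETM	9	TRUE
3CPL	Influenza virus peptide NP 366-374 with substitution M6A	ASNENAETM	9	TRUE
3BUY	Epitope of PB1-F2	LSLRNPILV	9	TRUE
3CC5	Nonameric peptide from Melanocyte protein Pmel 17	KVPRNQDWL	9	TRUE
3CCH	Nonameric peptide murine gp100	EGSRNQDWL	9	TRUE
3CH1	Nonameric peptide chimeric gp100	EGPRNQDWL	9	TRUE
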