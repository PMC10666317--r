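name	category	length_bp	start_codon	stop_codon	amino_acids	introns	copies	pseudo
atp1	ATP synthase	1527	ATG	TGA	509	0	1	0
atp4	ATP synthase	579	ATG	TAG	193	0	1	0
atp6	ATP synthase	720	ATG	CAA(TAA)	240	0	1	0
atp8	ATP synthase	480	ATG	TAA	160	0	1	0
atp9	ATP synthase	225	TTG	CGA(TGA)	75	0	1	0
ccmB	Cytochrome c biogenesis	621	ATG	TGA	207	0	1	0
ccmC	Cytochrome c biogenesis	753	ATG	TGA	251	0	1	0
ccmFc	Cytochrome c biogenesis	1293	ATG	TGA	431	1	1	0
ccmFn	Cytochrome c biogenesis	1734	ATG	TGA	578	0	1	0
cob	Ubiquinol cytochrome c reductase	1170	ATG	TAA	390	0	1	0
cox1	Cytochrome c oxidase	1584	ATG	TAA	528	0	1	0
cox2	Cytochrome c oxidase	783	ATG	TAA	261	1	1	0
cox3	Cytochrome c oxidase	798	ATG	TGA	266	0	1	0
matR	Maturases	1968	ATG	TAG	656	0	1	0
mttB	Transport membrane protein	348	ATG	TAG	116	0	1	0
nad1	NADH dehydrogenase	978	ATG	TAA	326	4	1	0
nad2	NADH dehydrogenase	1467	ATG	TAA	489	4	1	0
nad3	NADH dehydrogenase	357	ATG	TAA	119	0	1	0
nad4	NADH dehydrogenase	1479	ATG	TGA	493	3	1	0
nad4L	NADH dehydrogenase	303	ACG(ATG)	TAA	101	0	1	0
nad5	NADH dehydrogenase	2013	ATG	TAA	671	4	1	0
nad6	NADH dehydrogenase	618	ATG	TAA	206	0	1	0
nad7	NADH dehydrogenase	1185	ATG	TAG	395	4	1	0
nad9	NADH dehydrogenase	573	ATG	TAA	191	0	1	0
rpl10	Ribosomal proteins (LSU)	492	ATG	TAA	164	0	1	0
rpl2	Ribosomal proteins (LSU)	993	ATG	TAA	331	1	1	0
rpl5	Ribosomal proteins (LSU)	549	ATG	TAA	183	0	1	0
rpl16	Ribosomal proteins (LSU)	NA	NA	NA	NA	0	1	1
rps12	Ribosomal proteins (SSU)	378	ATG	TGA	126	0	1	0
rps13	Ribosomal proteins (SSU)	351	ATG	TGA	117	0	1	0
rps14	Ribosomal proteins (SSU)	303	ATG	TAG	101	0	1	0
rps3	Ribosomal proteins (SSU)	1686	ATG	TAA	562	1	1	0
rps4	Ribosomal proteins (SSU)	819	ATG	TAA	273	0	1	0
rps7	Ribosomal proteins (SSU)	447	ATG	TAA	149	0	1	0
sdh3	Succinate dehydrogenase	312	ATG	TGA	104	0	1	0
sdh4	Succinate dehydrogenase	387	ATG	CGA(TGA)	129	0	1	0
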