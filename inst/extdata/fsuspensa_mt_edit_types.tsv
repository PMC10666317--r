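category	from_codon	to_codon	count
hydrophilic-hydrophilic	CAC	TAC	6
hydrophilic-hydrophilic	CAT	TAT	15
hydrophilic-hydrophilic	CGC	TGC	7
hydrophilic-hydrophilic	CGT	TGT	29
hydrophilic-hydrophobic	ACA	ATA	3
hydrophilic-hydrophobic	ACC	ATC	1
hydrophilic-hydrophobic	ACG	ATG	3
hydrophilic-hydrophobic	ACT	ATT	3
hydrophilic-hydrophobic	CGG	TGG	28
hydrophilic-hydrophobic	TCA	TTA	72
hydrophilic-hydrophobic	TCC	TTC	31
hydrophilic-hydrophobic	TCG	TTG	38
hydrophilic-hydrophobic	TCT	TTT	38
hydrophilic-stop	CAA	TAA	1
hydrophilic-stop	CGA	TGA	1
hydrophobic-hydrophilic	CCA	TCA	6
hydrophobic-hydrophilic	CCC	TCC	6
hydrophobic-hydrophilic	CCG	TCG	3
hydrophobic-hydrophilic	CCT	TCT	20
hydrophobic-hydrophobic	CCA	CTA	44
hydrophobic-hydrophobic	CCC	CTC	9
hydrophobic-hydrophobic	CCC	TTC	6
hydrophobic-hydrophobic	CCG	CTG	31
hydrophobic-hydrophobic	CCT	CTT	20
hydrophobic-hydrophobic	CCT	TTT	14
hydrophobic-hydrophobic	CTC	TTC	4
hydrophobic-hydrophobic	CTT	TTT	10
hydrophobic-hydrophobic	GCC	GTC	2
hydrophobic-hydrophobic	GCG	GTG	7
hydrophobic-hydrophobic	GCT	GTT	2
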