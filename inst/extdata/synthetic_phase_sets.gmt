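G1/S	synthetic example phase set	geneA01	geneA02	geneA03	geneA04
S	synthetic example phase set	geneB01	geneB02	geneB03	geneB04
G2/M	synthetic example phase set	geneC01	geneC02	geneC03	geneC04
M	synthetic example phase set	geneD01	geneD02	geneD03	geneD04
M/G1	synthetic example phase set	geneE01	geneE02	geneE03	geneE04
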