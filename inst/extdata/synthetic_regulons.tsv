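TFX1	geneA01	Activation	synthetic
TFX1	geneB01	Repression	synthetic
TFX2	geneC01	Unknown
TFX2	geneD01	Activation	synthetic
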