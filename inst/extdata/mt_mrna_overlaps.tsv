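# CDS intervals shared by two genes; footprints with 5' ends here are ambiguous and excluded from both
gene_a	gene_b	start	end
ATP8	ATP6	8527	8572
ND4L	ND4	10760	10766
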