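>oligo_dT_modified cDNA synthesis primer; poly-T broken by an internal C; 3' degenerate base omitted
AAGCAGTGGTATCAACGCAGAGTCGCAGTCGGTACTTTTTTCTTTTTT
>lib_adapter_A 454 library adapter, synthetic example
CGTATCGCCTCCCTCGCGCCATCAG
>lib_adapter_B 454 library adapter, synthetic example
CTATGCGCCTTGCCAGCCCGCTCAG
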