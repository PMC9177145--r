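structure_id,accession,allotype,group,peptide_length,note
6ULI,6ULI,C*08:02,C1,9,C*08:02 with KRAS G12D 9mer (binary complex)
1EFX,1EFX,C*03:04,C1,9,
5VGE,5VGE,C*07:02,C1,9,
4NT6,4NT6,C*08:01,C1,9,
6ULK,6ULK,C*08:02,C1,10,G12D 10mer; descriptors measured at p9 (pOmega-1)
7SU9,7SU9,C*05:01,C2,9,C*05:01 with A18L 9mer (TCR9a complex)
1QQD,1QQD,C*04:01,C2,9,
6JTO,6JTO,C*05:01,C2,10,G12D 10mer; descriptors measured at p9 (pOmega-1)
5VGD,5VGD,C*05:01,C2,9,
5W6A,5W6A,C*06:02,C2,9,
5W69,5W69,C*06:02,C2,9,
5W67,5W67,C*06:02,C2,9,
6ULR,6ULR,C*08:02,C1,9,TCR9a complex of 6ULI peptide; alternative measurement source
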