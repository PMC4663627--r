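>pos_x40 synthesized positive-stranded sRNA, 5'->3'
CGUACGCGGAAUACUUCGAUU
>neg_x45 negative-stranded sRNA re-oriented to 5'->3' (reverse of the printed 3'->5' form below)
UCGAAGUAUUCCGCGUACGUU
>neg_as_printed printed orientation (reads 3'->5' against the positive strand); not used by the scan
UUGCAUGCGCCUUAUGAAGCU
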