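>ds98-197 homologous sequence, 197 nt
ctggtcataatcatggtggcgaataagtacgcgttcttgcaaatcaccagaaggcggttcctgaatgaat
gggaagccttcaagaaggtgataagcaggagaaacatacgaaggcgcataacgataccactgaccctcag
caatcttaaacttcttagacgaatcaccagaacggaaaacatccttcatagaaattt
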