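>ds98-931 homologous sequence, 931 nt
gaacggaaaacatccttcatagaaatttcacgcggcggcaagttgccatacaaaacagggtcgccagcaa
tatcggtataagtcaaagcacctttagcgttaaggtactgaatctctttagtcgcagtaggcggaaaacg
aacaagcgcaagagtaaacatagtgccatgctcaggaacaaagaaacgcggcacagaatgtttataggtc
tgttgaacacgaccagaaaactggcctaacgacgtttggtcagttccatcaacatcatagccagatgccc
agagattagagcgcatgacaagtaaaggacggttgtcagcgtcataagaggttttacctccaaatgaaga
aataacatcatggtaacgctgcatgaagtaatcacgttcttggtcagtatgcaaattagcataagcagct
tgcagacccataatgtcaatagatgtggtagaagtcgtcatttggcgagaaagctcagtctcaggaggaa
gcggagcagtccaaatgtttttgagatggcagcaacggaaaccataacgagcatcatcttgattaagctc
attagggttagcctcggtacggtcaggcatccacggcgctttaaaatagttgttatagatattcaaataa
ccctgaaacaaatgcttagggattttattggtatcagggttaatcgtgccaagaaaagcggcatggtcaa
tataaccagtagtgttaacagtcgggagaggagtggcattaacaccatccttcatgaacttaatccactg
ttcaccataaacgtgacgatgagggacataaaaagtaaaaatgtctacagtagagtcaatagcaaggcca
cgacgcaatggagaaagacggagagcgccaacggcgtccatctcgaaggagtcgccagcgataaccggag
tagttgaaatggtaataagac
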