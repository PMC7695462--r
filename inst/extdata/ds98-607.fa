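>ds98-607 homologous sequence, 607 nt
gaagtcatgattgaatcgcgagtggtcggcagattgcgataaacggtcacattaaatttaacctgactat
tccactgcaacaactgaacggactggaaacactggtcataatcatggtggcgaataagtacgcgttcttg
caaatcaccagaaggcggttcctgaatgaatgggaagccttcaagaaggtgataagcaggagaaacatac
gaaggcgcataacgataccactgaccctcagcaatcttaaacttcttagacgaatcaccagaacggaaaa
catccttcatagaaatttcacgcggcggcaagttgccatacaaaacagggtcgccagcaatatcggtata
agtcaaagcacctttagcgttaaggtactgaatctctttagtcgcagtaggcggaaaacgaacaagcgca
agagtaaacatagtgccatgctcaggaacaaagaaacgcggcacagaatgtttataggtctgttgaacac
gaccagaaaactggcctaacgacgtttggtcagttccatcaacatcatagccagatgcccagagattaga
gcgcatgacaagtaaaggacggttgtcagcgtcataagaggttttac
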