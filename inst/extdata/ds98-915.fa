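>ds98-915 homologous sequence, 915 nt
gaagtcatgattgaatcgcgagtggtcggcagattgcgataaacggtcacattaaatttaacctgactat
tccactgcaacaactgaacggactggaaacactggtcataatcatggtggcgaataagtacgcgttcttg
caaatcaccagaaggcggttcctgaatgaatgggaagccttcaagaaggtgataagcaggagaaacatac
gaaggcgcataacgataccactgaccctcagcaatcttaaacttcttagacgaatcaccagaacggaaaa
catccttcatagaaatttcacgcggcggcaagttgccatacaaaacagggtcgccagcaatatcggtata
agtcaaagcacctttagcgttaaggtactgaatctctttagtcgcagtaggcggaaaacgaacaagcgca
agagtaaacatagtgccatgctcaggaacaaagaaacgcggcacagaatgtttataggtctgttgaacac
gaccagaaaactggcctaacgacgtttggtcagttccatcaacatcatagccagatgcccagagattaga
gcgcatgacaagtaaaggacggttgtcagcgtcataagaggttttacctccaaatgaagaaataacatca
tggtaacgctgcatgaagtaatcacgttcttggtcagtatgcaaattagcataagcagcttgcagaccca
taatgtcaatagatgtggtagaagtcgtcatttggcgagaaagctcagtctcaggaggaagcggagcagt
ccaaatgtttttgagatggcagcaacggaaaccataacgagcatcatcttgattaagctcattagggtta
gcctcggtacggtcaggcatccacggcgctttaaaatagttgttatagatattcaaataaccctgaaaca
aatgc
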