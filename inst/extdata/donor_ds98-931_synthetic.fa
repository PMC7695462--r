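>donor_ds98-931_synthetic synthetic 3000 nt donor; ds98-931 homology at [1000,1931) 0-based
ctgaaattgagactggacgcacagctataaatacggactcccacaacaatatagactaaccttgccgcaa
gttgtataatttgttctcatgtcagagtattttggtctctatgcggatcctgccgacacaacccgttcag
tcccttaaattcgctattgtacataaaccgaggcgttgcggatttgaactagcaacctcattaggggagg
agattaactcgctcatccactcgctggggattgcggcgtcccgaacgccgatcccggcacggatctacag
cggactaaaagtgcagctgtctggatgtgaggagcatactgaaacgtgcaaacgtaccaagtctgcatga
ccgacgagagcatcggggcttcgtactagtgataaaaagtcttttaaaggtggagtagttgtgcgcggtt
ttagttctaaggtggttgtagcgctctcgcgcgtaatgtggcactacgagaggagacgttcgatcgagga
cgcacagggtaccaagaggttatgctatatgctgtggtagtactcttgacgggactaaagggcgagtcgt
cgccatcgtacgggccgacctcatcgatgcaggattgcaatgagtgacatgatcgggctggacagcccga
gaggcagcgaatcagtacctattaagcatagtaggcgagagttggcaatcggtcgtccctcttcaaaagc
tcacaatttagatacgcaggccatgtaactacgtttcagtgataatgatgatttgctaacggcgaatgtc
agggacctcaatgttaacaatccatggctccatgtcgccgcggggaacatgagtatacacaaaatcaaat
agtcggttggccagttgttgcgcgcttgacctgattccaggagaccctctttcgtcacgctccgcgacct
ccggccagtggtcttaggaaagaaaggatattaccaagtgcattaacgggcgatggaccatgggggtggg
ccgctccccctggtactagcgaacggaaaacatccttcatagaaatttcacgcggcggcaagttgccata
caaaacagggtcgccagcaatatcggtataagtcaaagcacctttagcgttaaggtactgaatctcttta
gtcgcagtaggcggaaaacgaacaagcgcaagagtaaacatagtgccatgctcaggaacaaagaaacgcg
gcacagaatgtttataggtctgttgaacacgaccagaaaactggcctaacgacgtttggtcagttccatc
aacatcatagccagatgcccagagattagagcgcatgacaagtaaaggacggttgtcagcgtcataagag
gttttacctccaaatgaagaaataacatcatggtaacgctgcatgaagtaatcacgttcttggtcagtat
gcaaattagcataagcagcttgcagacccataatgtcaatagatgtggtagaagtcgtcatttggcgaga
aagctcagtctcaggaggaagcggagcagtccaaatgtttttgagatggcagcaacggaaaccataacga
gcatcatcttgattaagctcattagggttagcctcggtacggtcaggcatccacggcgctttaaaatagt
tgttatagatattcaaataaccctgaaacaaatgcttagggattttattggtatcagggttaatcgtgcc
aagaaaagcggcatggtcaatataaccagtagtgttaacagtcgggagaggagtggcattaacaccatcc
ttcatgaacttaatccactgttcaccataaacgtgacgatgagggacataaaaagtaaaaatgtctacag
tagagtcaatagcaaggccacgacgcaatggagaaagacggagagcgccaacggcgtccatctcgaagga
gtcgccagcgataaccggagtagttgaaatggtaataagactagcgcgattcacgccttcttcgggaggc
agattttcttataaagattgaaaacagattcgtccgttctgcgagccggatttgtctggtaggttagcta
gtatcatgcaacttatgacgttcacttaactcgaataccgagcggtttataatatgtccgtgctatccag
ttcggacaagccctccgaagacggccctcggccgttgggtcggtgtcatttagagctacggacggtttta
taccaatatatatgattggccatggacaaactcgggagaaggtgagcggccatagcaggtactatgtaat
ccgccgtccttttcgaatgacgcaatgtccatgctcacgccagcagttccccgtaagagatcacagttct
ccaataaccggtaatacagcgcgccgacatcgacagtcggttgtctgcatgatctctagcatattcggat
acgggccacgctggaaatccatcgtgcatttttggttatcgcttgacgcctatgggtaaccagtcctcct
acgtacctaagagcgctcgcaaggggaccagtgaaatcagcctaacacgacctataacatggggtgtcta
ccgctgacgagagtgtgcctctgctcgtagtcacgccggacccatctttgcaatgaccgcgccgaaacat
gttagagttaggttcgccactgcggacccgtacatcaatcctcctggatggcttacgttccccatttgtc
ttttgaccaaggaagctgtaggagagtagcgtccaatgtcgcgtaaaaaggcccctcacgaactctgtct
ccggtatgcacctgtcttatgcagagggcgctcaattaacaacacgtaaaccggagtaggagacattttc
ggtgatcaagaccaaaggtataggctatcaagattaagcattgcactaggtaggtaatgtgtcgacagca
attattggctatgaccccctgtttctcatccccaatacggagatctatgcacagtgggtagtcttgatgc
atttagtctcttaaaacatactaccgaggtgtcccacagtataggagccggggtggatgg
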