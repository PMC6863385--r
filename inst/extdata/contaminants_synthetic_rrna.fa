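>syn_rrna_18S_like synthetic rRNA-like contaminant (random sequence)
AGCGGCGGTCGACGTGAGGGGCTGCGGATCACCCTACGCCCTGCGGATATATAATAGTTGATGCAGGTAT
CCACGCCGCGCGCCCTCTCAATCACGCGAACATGAAAGTCCACGGTTTTCTGCCCCCCCTCTGCAGTTAC
CACCCTTGACCCGGCCGATGCTTTGCGTCGCTGCCGCGACGAGTAGCTTGACAATGCACGGTTGTGGACT
TGCGGCGAGGGCACCCCTTTAGAACCAACGCCAGCGAGAACTTCACGGGTCTATGATGTGTGATTTCATC
TCCGTGCCCCCCCATCGGTACCGCACCAGGTAGGTTACCGCGAACATCGAAATGCAGTGCTATTACAGAT
GACCGTGCGGGTAGCCACGCTCGCCCGGACTATCTTCTCACGTTGACAGCGCGGCGTTGTGGCTTGTGCA
ACTTCCACGCTGAGAGGGCAGGCCGGTCTGTCGTGGGGGACGTCGCCACGCCTCTGCGTCTCTCTGGGGC
CGGTTCTACCCGAAGCCCACGTTGGAACCAATGGGCTACATATGGGAGGGTCTAGGTGAACCTGCATCTT
GCAAGAGTAGACATGCAGCGATTAGGAAGCCCCCATACCCGCTAGACTCCGGGTTGGTGTGGGGGAGGAG
GCTTGCGGGACACCCTTCGGCTGAGACTGGACTATGGACCAATTTACTCAGGGAGTAGCTAGAGCCGAGT
GGAGCGGGTAAGTACCCCGAACCGCTGCGCAAACGTCTCCCTGGGTGGCCGCGCCAAAGCCACTTTTGAG
TAGCCTTTTGAGACACGGTCGTGGCCTTGGTCCTTTACACAGAGCCTACCCTGTGACCAGGCCGCAGCTC
CGACCCGTTGGTCGAAATTCGTCACGCGTCTCGCACCCGTCCTCCCCTTTTGGTGGCAAGCGAGGGCCTT
CGCGCCGGAAAGCTGGGCAGCGCTAAAGGGGCGTGACCCTTTGACCAGAGTCGAGCTCGGTAGTTGTGCG
TACTCCCCATTTCACGCCCAGATATATACCCCCCAGTTTCGGACTATCGGGCAGCTGTCCTGCAAGAGGG
TGGGATGGTCCCTGCTTCCCGTTCACTTTCCCTGCGCATACATCTTTGGCAGGTAGTTGAGTGTCGTGCC
AGGGACCGGACGAGTCACCATCCTGCGATCTGTAGAGTGGCGAGTCGGACGAAGTCACACGACGAACTAG
AGGCCCCCTCTTGCGGCTGCCACGACCCCAGCACGCAAGTTCACCCGTCTGCAGTGGGCTAATTGCCCCC
AAGAATGCACGTATCAAGCGGCGCAGTGGACAGACGCCATCTTCACTCTACCTCACACTCGTCGTTGGGG
GATACTACCCCCTTTTTAGACAAAATCCGCAGGGGACCTGACCACACGTCCCTATCGGAGGAACAGCTGC
GACGGGTCCACCCACCGACCAAGCGACGGAGCGATACTGTCCTGCGGAGCGGGCATCGGCGGACAAGGCC
TGCCCCCTGTGATTGAGCCCATCCGCTGCCGCGTCCAGGCAGGACTACAAGGCTGCCGGGCCCAGCCTGG
GCTGTGAAAGACGCCTGAAGGGATCCGCGTTGCCGATCACATATACCCACGCCAAGGTCATTTTAGGAGC
TAGGGGAGCCCCTTCCCCCCCTAGTCAGGGTATGTTGTTCCCGCTTAAACGGGAACAGATCTAGCGCTTA
GACGGAGAGATGTGCCCGTAACCGACTGACGCACTCCACAGCTGTCCGTCGGTGGATTCACTCTGGTAGG
AGACGGGGGGGATCTTACTCACCCGGCCACGAGTTAAGGGAAGGAACTGC
>syn_rrna_28S_like synthetic rRNA-like contaminant (random sequence)
TGGGCTGAAGTACCGATCATGCCCCTTACGCCCCCGTAGTTAGATGATCAGGAGCAAAGACCGTCCTACG
GACCGGCCCGTTTGACACCCTTTCATTCTATATCAGGGTGCGAGACGAGGCCTTCCCCCAAGGCAACGCC
TACGGTGTCGCAGCCCGTAACGTCAGCGGGCAAAGAGGCCCGACAGGCGCGTTTTGTGCTTACTACGAGC
GCCAGCGTGGACGTCCTCTTCATTGACTCGGGAGCCGCAACGGCAGGCAACACGCTTGTGCTTACTACCC
CCGGGAGTGCGAAAGCTTTCGGTTAGCGTGGTCAGCCGTCTCTTTGGCTCCTGCGTACGTGTTTTTAGGA
GCAATCGCGCGAGCCGGTAGTGGACCCGTTCCTCCTGAGTAGCGTTTCTGCTCGTCTCAATCAGTAGGCA
CACCCATGCGTGTCGCGACGGCTTCTCGGGACCTCGCATGCGCAGCCCCGCTCCGTCGGCATCAGGGTAC
GTAGGCCACAGGCAGCCAGGACCTCCCTTAGCTGATAGAACCCCTACCTAGAGGCTAGCGGCGCTAGTTC
TCGCGCGTTTGACTCAAGTGCCGCAGACGGCCCGGTCGAGGGCGAAGCAGCCATTATCCCTATTCTTGGG
CCTCTGCGCCCATCCAATCCGTGCAGCGCTCGCAAACAACCCCGGGCGGGAGAGACCGGCCACGGTGGAG
GGTCTTCGTATGTCGTCGAAGGCCTTGGTGCACGCGACCTGACTCGATTGGGGAAATTACGCACAACACG
GTGGCGTAAGCCCGAGTTGCGAGCGCAGCATTCTCCAAGTTCTAGGGCTACAGAAGTATTTTTCGGCCGA
GCGCAGATGATGGCGCACGGCTTGGTAGGTCGTATGTCGGGACGGGGATCGGTGCACTCCTGACATCATA
GCATCCGGGACGCGCGCTAGTGTGCGACACTGGTTAGTTTATATCTCTCGCACTTCCCGTCCTTCCTACT
GCCCTCGCCCACCCCTACCCCCCGCTAAATCAGCTCCGCTTTTACTTCTTGGTCTGTGGAGTTGCAGCAG
CAATCTCACTACCGGCACAGAGGGGAACCTAGTGCTGACAAAAGCCCGCACGGCTCCCTCCGAATGGAAT
AAGGCGGAGAGGGACTGTCCGGCGCTGTCACCAAGTACTGTCCCGACTTGCCACGAAGGCTGACGTTTAT
CGCTAACTCCCTCACTGCACTCTCCGGAACCCGGGTGCCATGCGAGGCGTACTCGCTACCACGAACGGCT
ACATCGGGGTGCAGAGATCGCCGCCCCGCTTAGCACGCGCTCGCGGCTATTTGTGGGTACTTAGGCGTTC
TCCGACGAGTGCGCTTAGGCTCCCGGTCCGGAGTACGGTCGCGCCGCCGTCCGGTGAGCTATACTTAGGA
ATAGCAGGAAACCTCGTACGCTGCCTCCTGGCATTTAACTTCCATACTGTTGCGTTAGGCCTTCCACGGA
CCCGTCGACGCGTCTACGATCTGGCACAGAAATGGTCCCCCTGCGCCGAGAGCTCTGCAATCTCCCCCGT
GTCTTATCTGTATCACAACTAGCGCTTGGAACCTTAAAATTCCGATAGACTATGCGGCTGTAGCAAGTTC
GCCCACATGGAGCATCCCCGCGCCAACCATGCCTACCCCGCACATGAAGGCCCTACCTGCGGTCGCCAAA
CTTACGGACATTGACAGGGGTCATTCGCCGTTCGGGCAAGCGCCACCACAATGCTGCTACCACACTTTGT
TCAACGGGTTGATGGCGATCATAGTTATCTATGCAATCATATGGGGGTAGCTGGATACACCACCGGAGCC
CAGCCCTACCAAGCTCGGAACCTCATGGGGAGCAGTCGGCGTAGAACACGGGGGGGGGGCGGTGGACCAG
GTCCGTAGGTGCACGGAGGGGTCTCTAGGAACATCCTCTCTGCTCGCGGAGGGGCGTCGTTTACTCGCGT
CACGTGCAACCTCCTCCTGCGTGGCTCCTCCTAACAAACTGAGGTAGTTGGGGCAGATATCTCCTATGGC
CCACACAACGATCTTCGGCGTGCTCGGTACTCCAAAGGACGCTGCCTTCGAAGCCTGCGGAGCGGTGCGA
TCGGATTTGGGTAAGCCACCAAATCCGAAGGGCACCGGGCCGTAGCGTCTGCGTAGCATACCCCGGCGGG
CCTTGGCTTCCTTGTAGTATCTTCGGCCCTAAACGACTTTAATCTCATCGCGAACGGCCTTAACGAGTCC
ATTTAGGTGCCGCGCAACCCCACTCAGACTATACCTATCAAGCTGGCTGACGACCAGGACAACGGCGGCG
CCCGAGGATCGCCGGCACGCTCAACAGTCCATGGGCACGTAATGGAGGACGACGGTTCAGGACCGATCGA
CCGGGTCAGTAAGAGGGCTTCCACAAAAGGGGTGCTGAAACATCGTACCTCAGAATCAGGCCGCCAAAGC
ACGTGGTCATGGCAGTGAGCTATGTAATGGAATCCCGGCCGTGTGCATGC
>syn_rrna_5p8S_like synthetic rRNA-like contaminant (random sequence)
GCACGGGTCGAGGATTCCGAGAAGGTGTGGACATCTCTGCGCCCGACGTACGACCCGCACACGCAAAAGA
TCCACGCCGTCGTCGGCTCCCGCCGGGAGGACGCGCGGTCGTAGACCTTCCCGCTTGATTGCCCTCTCTT
GATGGAAAGAGTCAGAGTCA
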