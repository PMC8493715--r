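>TRGV4.1
AACAAGGGGACCCTACGTACCTTATTCGAGCATACGCGAGTGCTGGGTCTGAGAGGATCGTAACTATCTAATGTAGCTTC
GCCACGGCCACCAAGGCAGCTACCAATCGTGTGATGTAGG
>TRGV1.1
CGTGCAGGAACTAGCATGTATTATTCGCCCCGTCTATAATACTTGGTCGATAGAGGATCATAAAGCACAAATAACCTTCC
GTCGCGCGCGCTATAATAATGCATCGTCTACGCTTGTTCA
>TRGV3.1
TAGGCGCTCCACGTACGTCCGTAACCTACCGCATCATCAACCGCCAGTATTTGGTGGGACACACATTGTTTCGCGACAAT
GCGACCGATGGGTAATAGGACCACGTCCTGAAAGTGTGTT
>TRGV2.1
TGTGTTAGACAGAATCCGACATGGCCTCGACCTCTCTGATTATGCGTGGCCGAAGGCATCTCGATAGCAAGCCGGGGCAA
CCGCCTGGCAGACGTACGAAGCGTAGCCCTAATGTGTTTT
>TRGV2.2
TGTGTTAGACAGAATCCGAGATCGCCTCGACCTCTCTGTTGATGCGTGGCCGAGGGCATCTAAGTAGCAAGAAGACGCAA
CCGCCTGGCAGGCGTACGAAGCGCAGCGCTACTGTGTAGA
>TRGV2.3
TGTGTTACACAGAATCCGAGATCGCCTCGACCTCTCTGTTGATGCCGGGGCGAGGACATCTAAATAACAAGACGGAGCTA
CGGCGTGGTAGGCGTACGAAGCGTAGACCTAATGTGTTTA
>TRGV2.4
TGTGTTAGACAGTTTCCGAGATCGCTTCGACCGCTCTGTTCATGCCTGGCCGAGGGCATCTCGAGAGCTAGAAGGAGCAA
CCGCCTGGCAGGCGTGCGAAGCGTCGCCCTAATGTGTTTA
>TRGV4.2
AACATAGAGACCCTACGTACCTTATTAGACCATACGCGAGTGCTGTGTCTGAGAGAATCGTCCCTGTCTACAGTAGCTTC
CCGACGGCCACCAAGGCAGCTACGAATCGCGGGTTGTAGC
>TRGV1.2
CGTGCAGTCTCTAGCAGGTGTTATTCGCCCCGTCTGTAATACTTGGTCAATAGAGGATCACGTATCACAAATAACCTTCC
CTCGAGCGCGTTACATTAATCGATCGTCGACCCTTGTTGA
>TRGV3.2
GAGGCCCTCCTCGTACGTCCGTAACCTACCGCAGCGTCATCCGCCATTATTTGGTGAGACACTCAGTGGGTAGGGGCAAT
GCGACCAATGGGTAATGGGACCACGTCCTGTAAGTGTGTT
>TRGV2.5
TGTGTTAGACAGAATCCCAGATCGCCTCGACGTATCTGTTGATGCCTGGCCGAGGGCTTTTAAATAGCGAGGCGGAGCAA
CCGCCTGGTAGGCGTACGAAGCGTAGCCCTGATGTGTATA
>TRGV2.6
TGTGTTAGAAAGAATCTGAGATCGCCTAGACCTCTCTGTTGATGCCTGGCGGAGGGCATCTAAATAGCAAGACGGATCAA
CCGCCTTGCAGGCGTACGAAGCGTAGCAAAAATGTGTTAA
>TRGV2.7
TGTGTTAGACAGAATACTAGAGCGCCTCGACCTCTTTGTTGATTCATGGCCGAGGGCGTCTCGATAGCACGACGGAGCAA
CCGCCTGGCAGGCGTACTAAGCGTAGCCCTAATGTGTGTA
>TRGV2.8
TGTGTTAGACAGTTTCCGAGATCGCTTCGACCGCTCTGTTCATGCCTGGCCGAGGGCATCTCGAGAGCTAGAAGGAGCAA
CCGCCTGGCAGGCGTGCGAAGCGTCGCCCTAATGTGTTTA
>TRGV4.3
AACATGGAGACCCTACGTACCTTATTAGACCATACGCGAGTGTTGGCTCTGAGAGGATTCTAACTATCTAAAGAAGCTTC
GCGACGTCCCCCACGGCAGCTACGAATCGTGTGATGTAGA
>TRGV1.3
CGAGCAGGCCCTAGCAGGTGATATTCACCCCGTCTGTAATACTTGGCCGATAGAGGATCACGGATCACAAATAACCTTCC
GTCTCGCGCGTTAGAATAATCCATCCTCTTCGTTTGTTGA
>TRGV3.3
AAGGCCCTCCACGTACGTTCGTATCCTACCGCAGCATTAAACGCGATTATTGGGCGGGACACACAGTGGGTTGGGACAAT
GCGACCAAGGGGTAATAGGACCACGTCCTGAAAGTGTGTT
>TRGV2.9
TGTGTTTGACAGAGTCCGAGATCGGCTCGACCTCTCTCTTGATTCCTGGCCGCGGGCATCTCGATAGAAGGACGGAGCAA
CCGCCTGGCAGGCGTAAGAAGCATAGCCCTAATGTGTTTA
>TRGV2.10
GGTGTTAGACAGAATCCGAGATCGCCTCGACCTCCCTGTTGATGCCTGGCCGAGGGCATCTAAATAGCAAGGCGGAGCAA
CCGCATGGCAGGCGTACGAAACGCATCATTAATGTGTCTA
>TRGV2.11
TTTGTTAGACAGAATCCGAGATCGGCTCGACCTCTCTACTGATGCCTGGCCGTGTGGATCTCGATAGCAAGACAGAGCAA
CCGCCTGGCAGGCGTAGTAAGCGTAGCCCTAATGTGTTTA
>TRGV2.12
TGTGTTAGACAGAATCCGAGATCGTCTCGACCTGACTCTTGATGCCTTGCCGAGGGCATCTGGATAGGAAGCAGGAGCAA
CCGCCTGGCAGGCGTACGAAGCGTAGCTCTAATGTGTTTA
>TRGV4.4
AACATGGAGACCCTACGTCTCTTATTAGACCATACTCGAGTGCTGAGTCTGAGCGGATCGGCCCCATCGAAAGTAGCTTC
CCGACGGCCACCAAGGCAGTTACGAATCGTTTGCTGTAGA
>TRGV1.4
CGAGCAGGCTCTAGTAGGTGTTATTCGCCACGCCGGTAAAACTTGAACAATAGAGGATCATAAATCACAAATATCCTTCC
GTCGCGCGCGTTATAATGATCCATCGTCTACGCTTGTTGA
>TRGV3.4
AACGCCCTCCACGTACGTCCGTAACCTACCGAATCATCAACCGCCATTAATTGGCCGGACACACAGTGGGTTGGGACAAT
GCGACCAAGGGGTACTAGGCCCACATCCTGAAAGTGTGTT
>TRGV2.13
TGTGTTAGACAGAAACCGATATCGCCTCGACCTCTCTGTTGATGCCGGGCGGTGGGGATATCGATAGCAAGACGGAGCAA
CCGCCTGGCAGGCGTACGAGGCGTCGCCCTAACGTGTTTA
>TRGV2.14
TGTGTTAGACAGTTTCCGAGATCGCTTCGACCGCTCTGTTCATGCCTGGCCGAGGGCATCTCGAGAGCTAGAAGGAGCAA
CCGCCTGGCAGGCGTGCGAAGCGTCGCCCTAATGTGTTTA
>TRGV2.15
CGTGTTAGACAGAATCCGAGATCGCCTCTACATCTCTGGTGATGCGTGGCCGAGGGCATGTCGATCGCAAGACGAAACAA
CCGCCTGGCAGGCGTACGAAGCGTAGCACTAATGTGTTTA
>TRGV2.16
TCTGTTAGACAGAATCCGAGTTCGTCACGACCTCTCTGTTGCTGCTTGGCCGAGGGAATCTAAATAGCAAGACGGAGCAA
CCGCCTGGCATGCGTACGAAGCGTAGCCCTAAAGTGTTTA
>TRGV4.5
AACATGGAGACCGTACGTACGTTATTTGACCATACGCGAGTGCTGGGCCTGAGAGGAGCGTAACTATCGAAAGTAGCTTC
CCGACGGGCAGCCAGGCAGCTACGAATCGTGTGATGTCGA
>TRGV1.5
CGAGCAGGCTCGTGCAGATGTTATTCGCCCCGTCTGTAATACTTGGTCCATATAAGATCACGTATCAGAAATAACCTACC
GTCGCGCGCGTTATAATAATACATCGTCTACCCTTGTTGA
>TRGV3.5
AAGTCCCTCCACGTACGGACATAACCTACCGCATCATCAACCGCCATTATTTGTTCGGTCACACAGTGGGTTGGGACAAT
GCGAACAATGGGTAATAGGACCACGTCGTGTACGTGTGTT
>TRGV2.17
TGTGTGAGAAAAAATCCGAGATCGCCTCGACCGCTCTGTTGATCCCTGGCTGAGAGCATCTAAATAGCAACACGGAGCTA
CCGCCTGGCAGGCGTACGAAACGTAGCCCTAATGTGTTTA
>TRGV2.18
TGTGTTAGACAGAATACTAGAGCGCCTCGACCTCTTTGTTGATTCATGGCCGAGGGCGTCTCGATAGCACGACGGAGCAA
CCGCCTGGCAGGCGTACTAAGCGTAGCCCTAATGTGTGTA
>TRGV2.19
TGTGTTAGACAGTTTCCGAGATCGCTTCGACCGCTCTGTTCATGCCTGGCCGAGGGCATCTCGAGAGCTAGAAGGAGCAA
CCGCCTGGCAGGCGTGCGAAGCGTCGCCCTAATGTGTTTA
>TRGV2.20
TGTGTTAGACAGAATCCGAGATCGCCTCGACCTCTCTGTTGATGTCTGGCCGAGGGCATTTCGATAGCAAGACGGAGCAT
CCGCCTCGCCGGAGTACGAAGCGAAGCGCTCTTGTGTTTA
>TRGV1.6
CGTGCAGGCTCGAGCAGGTGTTATTCACCCCGTCTGTAATACCCGGTAGATAGAGGATCAAGTAGCGCAAATAACCTTCC
GTCGCGCGCGTTCTAATAATCCATCGTCTACGCTTGTTGA
>TRGV3.6
AAGGCCCTCCACGTACGACCGTAACCTACCGCATCATCAACCGCCAATATTTGGTGGGACATACACTGGGTTGGGACAAT
GCGAACAATGGGTAATAGTACCACGCCCTGTGTGTGTGTA
>TRGV2.21
TGTGTTAGACAGAATCCGATATCGCCTCGACCTGTCTGTTGATGCCTGGCCGATCGCATCTAAATAACTAGACGGAGCAA
CCGCCTGGCAGGCGTTCGAAGTGTTGCCCTAATGTGTTTA
>TRGV2.22
TGTGATAGACAGAATCCGAGATCTCCTCGATCTATCTGTTTATGCCTGGCCGTGGGCATCTCGATAGGAAGACGTAGCAA
CCGCCTGGCAGGCGTACTTAGCGTAGCCCTAATGTGTTTA
>TRGV3.7
AAGGTCCTCCACGTACGTCCGTAAACTACCGCATCAGCAACCGTCATTATTAGGTGGGACACAAAGAGGGTTGGGACAAT
GCGACCAATGGCGAATAGGACCACGTCCTGTAAGTGTGTA
>TRGJ1
GGGTTTAACCAATCACATAATGACCGCAAAAAACCTACCTTTGATTTGAGGTCAGAGAAT
>TRGJ2
ATGACTAAAACCCCGTCAGTTCACGCCGGCTCTATCACTTTTCGGCTTCCTACTTGGAAG
>TRGJ3
AGGCTTTCGTTCAACTGAGTAATACACCGCATCGAAAACTTTATATCTCCGCCACTTGAC
>TRGC
GGTTGACAAGACGGTGTTTTAAGGCTAAGCGGATCCCCCACTGGCTTCCGTGACAGTGGTCCGCAGCTTTTGCTTTTCTG
GCATTCGACTTGGCACACCATATGGTCAATAGATCCTCTGTTGATCGTTTGCTACTGCTTCGAAGGAGAT
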