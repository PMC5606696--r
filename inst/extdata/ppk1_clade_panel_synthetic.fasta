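>ref_IA clade=IA
CCCCCCGTCGCGGTGTTCTACACACAATCCTCCGACAGGTTGGGGCGAAGACTTGGAAGACCCCGTCTCT
ACCGTGGCTAATGGCTAGGGTCGATAAGACCTCCAAACGATCTGGGCTAATACGGGAGTGGGAATTTGGG
ACCTAATACCCGGGATACATATGACAAAGAGTGAGGCCCACGCGCTTCATCGTATCAGCATATTGCATTC
TAGAGCGGAGAACTTATGCCCAGATATTTTAACTAACAATGCATTTTGATAAGTTGTTGGCCCACGATGT
ATCGAGTCACCTGAAATCTA
>ref_IB clade=IB
CCGCCGGTCGCCGTTTTCCGCAGACGATTCTTCGACAGGTTGGGGCGAAGAAGTGGAAGACCCGGTCTCT
ACCGTGGCTAAGGCCTAGGGTCGATAAGACCTCCAAATGGTCTGGGCTTATACGGTACTGGGACTGTGGG
ACCTTATACCCGAGGTACATGTGACAAAGAGTGAGGCCCTCGCGCTTCATCGTATCAGCATATTGCATTA
TAGAGCGGGGAACTTATTCCCAGATATTTTAACTAACACTGCATTTTGGTAAGTTGTTGGCCCACGATGT
ATCGAGTCACCTGAAGCCTA
>ref_IIA clade=IIA
CCACCGGTGGCTGTGTTCCACACACAATTCTTCGACAGGCTGGGGGGAGGATTTGGAAGAGCCCTTCTCT
ACCGAAGCTAAGGGCTAACGCCGATAAGACCACCAAACGAGCTGGGCTTTTACGGTAGTGGTAAGATGGA
ACCCATTACCCGGGATACATGTGACAAAGATTAAGGCTCACGAGCTTCATCGCATCATGATTTTGCATTC
TAAAGCGGAGAACTTATGCCCTGATATTTTATATTACCATGTATTTTGGTAAGTTGTTGGCCCGCGATGT
ATCGAGTCAGCTGACGTATG
>ref_IIB clade=IIB
CCGCCGGTGGCGGGGTTCCACACACTATCCTTCGACAGGCTGGGGGGAGGATTTGGAAGAGCCCGTCTCT
ACCGAGGCTAAGAGCTAACGCCGATAAGACCTCCAAACAAGGTGCGCTTATATGGTAGTGGTAAGTTGGA
GCCTATTTCGTGGGATACATGTGACAAAGAGTAAGGCGCACGAGCTCCATTGCATCATCATTTTGCAATC
TAAAGCGAATTACTTATGCCCTGATATTTTCACTTACCGTGCATTTTAGTAAGTTGTTGGCCCGCGATGA
ATCGAGTCACCTGACGTCTA
>ref_IIC clade=IIC
CCGCCGGTGGCGGAGTTCCACACACAATTCTTCGACAGGCTGGGGGGAGGAATTGGAAGAGCCCGACTCT
ACCGAGGCTAAGGGCTAGCGACGATAAGACCTCCAAACGAGCTGGGCTTATACGGTAGTGATAAGTTGGT
ACCTATTACCCGGGATACATGTGACATAGAGTAGGGCGCAGGAGATTCATCGCATGATCATTTTGCATTC
TAAAGCGTAGAACATATGCCCTGATAATTTAACTTAGCATGCATTTTGGTAAGTTGTTGGCCCGCGGTGT
ATCGAGTCACCTGACGTCTA
>ref_IID clade=IID
CCGCCGGTGGCGGTGTTCCACACACAATTCTTCGACAGTCCGGGGGGAGGATTTGGAAGAGCCAGTCTCT
ACCGAGGCTAAGGGCTAACGCCGATAAGACCTACAAACGAGCTGGGCTTATACGGTAGTGGTAAGTTGGA
ACCTATTACCCGGCATACATGTGACAAAGAGTAAGGCGCACGAGCTTCGTCGCATCATCATTCTGCGTTA
TAAAGCGGAGAACTTATGCCCTGATATTTTAACTTACGATGCATTTTGGTTAGTTGTTGGCCCGCGATGT
ATCGAGTCACGTGACGTCTA
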