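>APC_cds_synthetic_context synthetic 261-codon coding context
ATGTGGACCTGGCTGGCCCCGGAGAACCCGTATCAAACCCTGGCACGCTATCGCCAACAA
ACCCACTATTTCAAACCGATCGGTAGTAAACGCAAACTGATCTTCGTTAACCAATATGAG
AACGCCCACATCGCAATGGATGGTAAATTCCCGGCCAAAAGTCAATTCGATGGTCACAAA
CGCGAGCAAACCATCCCGCCGAAATGGCAAACCATGTTCGCCCACGATATGGTTCAAGCA
CCGATCCCGGTTGGTCTGCGCTATCAAGCAAACTGGGTTCCGGATCTGGAGCTGGATGAG
CACTGGGCAGATCTGCCGCCGGTTATGGTTGGTCACTTCTATTATACCGATAAAGATAAC
CAAGGTAACATGCAAAAACACACCATCAGTTTCGCCCAAATGAGTAAAATGGTTTGGAAC
ATGCAAGTTTTCATGATCAAACGCTGGTATGTTATGGCCTTCCACGCAGAGATCCAACAA
AAAATCCCGAACCACCACAGTCTGTATAAACACGAGGCCCACCGCAACGCAAGTTGGGAG
GGTTATCACACCGCCGGTCGCAAAGCATGGACCGCAATGATCTTCATGTATGTTCACGTT
AAAAGTGCAACCGGTAGTTTCGTTCAAAACCAATTCGATGCATGGGAGTTCGATTTCGCA
GATGAGCGCAACATCATGCAAAAACACAGTAACCGCGCCGCAAAAGATGAGCAAGCTACT
GAAGCCGAGCGTAGTTCCGGACTGCAAAATAAAAGTAACCCGGTTACCAAAAGTGATGAT
TAA
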