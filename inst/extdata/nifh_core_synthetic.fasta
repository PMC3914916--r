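>nifh_core_synthetic length=320 note=synthetic_coding_core_cys54_cys93
CTTCCAGTGGTCCGTCTGGTCCCAATCCACGCGCTCATACAGGAATGCGGGGCTAGAAGC
ATGGCTCAGGTCGTCACTATTCACAACTACAACCCTCTCCTACTAACTGGTTTACTTGTC
ACAGATTTCGAGGTTCCACAAATCTGTCAGATTAGAGGTTGCGCCATTAACTTAGGTAGC
AAATGCCGTGGCTCCTGTAGCGGCTCGTATCCGGAGCGAAACTGTGTCTATCGGTTTTGG
TTTATGTGCGTGTTCTACAAGGGAAGCCACTTAATCTGTAGACGGCCACACCGGGAGTTT
GTTCCCACCAAGTCTAGTGA
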