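>synthetic_bcl2_cds synthetic 720-nt coding sequence (BCL2 stand-in)
ATGCGAGCTCATGGGGCCAATCATCCCGAGGCTCGGATAGGAGTTTATATTCTGATCCCT
AATCTGACCAAACCCGGGCCTCCTTCCCTAGATTTCCGTTGCATTTTCTCTGACGCTACA
GGTAATGTTAGGTACAATTTCCTGATCCTAGTGACGATTAAAGTTGCCGAGAAGGCCTCT
GCTAAAACTCCCGTCATCCGCGAAACCGCAACTTTATTCAAAATTTGGAACGATTCAGCG
CTTAACACTGTAGGTCAGGCTGCAGGCACCGAATCGCAATTGCAATTAGGTATATTTCGC
TATCCGTACATCGCTCTACCGATCGAGGTTGGACGGGCACTCCCTTACGCTTACGACTAT
ACAGCTACCAAGGAAAGCGATATATTGGCCCCTTATTACATAGTCAGTTACGTCGTCTCC
CAACAGTCATTGGCCACCTACCGTTCACCGTGGACCCTCTACATTTCTTTCAGCCGTTGT
CAGACAAGAGGTTTACTGTTTGTGGAAGGCGTATTCACGCAATCGAGCCCCAGCCTAGTC
GGCCAAGTTCACGTGTCTCGATGGTTGCGAGTGCGGTTCTTTGAGTTGGCGCGGGGTGTA
GTAGCAGCGATCCTAAAGGAAGCTGGTTGCAACACTCATCTGCCCCACAAGACAGTTATG
ATTGAAACGGAAGCACGACTTGAAAGGGCGTGCTGGAGATCGCCCCTGACCATGACGTAA
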