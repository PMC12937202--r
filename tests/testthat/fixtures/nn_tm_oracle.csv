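sequence,na_mM,oligo_nM,tm_oracle
AAGCCCAATAAACCACTCTG,25,50,48.3568
TGGCCGAATAGGGATATAGG,50,500,54.9383
AACGACATGTGCGGCGACCC,200,250,71.3007
GCGACAGTGACGCTTTCGCC,100,500,67.4986
TTGCCTAAACCTATTTGAAG,100,50,50.5043
GTCTAGCAGCCGCAGTAAGG,50,50,56.6934
CAATACCTCGTCCGTGTTAC,50,50,52.2345
GACCAAACAAGACGTCCTCT,200,50,60.4298
AATGTTTAAATGACCCTCTC,100,250,52.4426
CATAAAACCTTTCTACTATG,200,250,51.4805
TTCCGCAAGAATCAACAACT,25,500,51.814
CAATGGCGCGTCGTGAATAA,50,500,58.9629
GCGACGGCTGAGACGAACGG,50,500,65.3784
GCGTGAATGAAGCGCTTAAA,50,500,57.0949
AGCTCAGGAGCCAGTCCCCT,25,50,57.0678
GTCGCATATCCTGGCCACTG,100,50,60.3914
GGTGAAGCGAATGGTATCGA,200,50,60.7119
CGTAGGAGGTGTGCCTTCGT,25,250,56.8447
GCTGTTTCTCAGGACGCCCA,25,50,55.4684
TATTCTTTCCAATCCTACAT,50,250,46.937
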