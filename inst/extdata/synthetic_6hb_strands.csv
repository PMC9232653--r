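label,sequence,terminal5,terminal3,cycle_order
I,TATCTTAACCATGTGATTTCTATGTATATATTTGACTTTGTAATATACAT,phosphate,hydroxyl,1
II,AAGTTTAGAACCTTAGTTTCCTTTTTATTAAAAAGTAGGCATCTCTTTTT,phosphate,hydroxyl,2
III,ATTTCACATTAGCAGAATATATTCTTATTAGATTATTACTTTATTTTAGT,phosphate,hydroxyl,3
IV,TTCTGCTATCATGTATTTAAATATACCCGTTTTTGATTAGTACCTTTATA,phosphate,hydroxyl,4
V,ATTATAATTTATCAAAACCCGATTTTTTCGTTTTAATTGTTTAGACTATC,phosphate,hydroxyl,5
VI,GCTTTATTAATTAAAATCTCTATGTTTTAGCGGACTTTATTTACTGTTAA,phosphate,hydroxyl,6
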