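id,tag,smiles
B001,AGAGA,NCC
B002,CTCTC,NCc1ccccc1
B003,GAGAT,C1COCCN1
B004,TCTCT,Nc1ccccc1
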