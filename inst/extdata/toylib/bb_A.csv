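id,tag,smiles
A001,AACCG,CC(=O)O
A002,TTGGC,CCC(=O)O
A003,CATGC,OC(=O)c1ccccc1
A004,GTCAA,OC(=O)C1CC1
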