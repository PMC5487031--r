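assay_id,forward,probe,reverse
Astast,GATTAGAGGAATAGTAGAGAG,AGGAGTAGGGACAGGATGAACT,CTGATGCTAAAGGGGGATAA
Paclen,AACTAGAGGAATAGTTGAAAG,AGGAGTGGGTACTGGATGAACT,CCGCTGCTAGAGGAGGATAA
AstlepI,AACTAGGGGTATAGTAGAGAG,AGGAGTAGGGACCGGATGAACT,CTGATGCTAAAGGGGGATAA
AstlepIII,AACTAGAGGTATAGTAGAGGG,GGGTGTAGGAACTGGATGAACC,CTGATGCTAGGGGAGGATAA
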