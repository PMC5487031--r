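sample_id,assay_id,dilution_factor,ct,role
LAKE1_F1,Astast,1,33.8,unknown
LAKE1_F1,Astast,1,34.1,unknown
LAKE1_F1,Astast,10,37.2,unknown
LAKE1_F1,Astast,10,37.5,unknown
LAKE2_F1,Astast,1,39.6,unknown
LAKE2_F1,Astast,1,ND,unknown
LAKE2_F1,Astast,10,ND,unknown
LAKE2_F1,Astast,10,42.1,unknown
NTC_1,Astast,1,ND,ntc
NTC_2,Astast,1,ND,ntc
BLANK_1,Astast,1,ND,extraction_blank
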