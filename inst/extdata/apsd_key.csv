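instrument,item,scale,reverse
APSD,1,IMP,FALSE
APSD,2,none,TRUE
APSD,3,CU,FALSE
APSD,4,IMP,FALSE
APSD,5,NAR,FALSE
APSD,6,none,FALSE
APSD,7,CU,TRUE
APSD,8,NAR,FALSE
APSD,9,IMP,FALSE
APSD,10,NAR,FALSE
APSD,11,NAR,FALSE
APSD,12,CU,TRUE
APSD,13,IMP,FALSE
APSD,14,NAR,FALSE
APSD,15,NAR,FALSE
APSD,16,NAR,FALSE
APSD,17,IMP,FALSE
APSD,18,CU,FALSE
APSD,19,CU,TRUE
APSD,20,CU,FALSE
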