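instrument,item,scale,reverse
BFI,1,E,FALSE
BFI,2,A,TRUE
BFI,3,C,FALSE
BFI,4,N,FALSE
BFI,5,O,FALSE
BFI,6,E,TRUE
BFI,7,A,FALSE
BFI,8,C,TRUE
BFI,9,N,TRUE
BFI,10,O,FALSE
BFI,11,E,FALSE
BFI,12,A,TRUE
BFI,13,C,FALSE
BFI,14,N,FALSE
BFI,15,O,FALSE
BFI,16,E,FALSE
BFI,17,A,FALSE
BFI,18,C,TRUE
BFI,19,N,FALSE
BFI,20,O,FALSE
BFI,21,E,TRUE
BFI,22,A,FALSE
BFI,23,C,TRUE
BFI,24,N,TRUE
BFI,25,O,FALSE
BFI,26,E,FALSE
BFI,27,A,TRUE
BFI,28,C,FALSE
BFI,29,N,FALSE
BFI,30,O,FALSE
BFI,31,E,TRUE
BFI,32,A,FALSE
BFI,33,C,FALSE
BFI,34,N,TRUE
BFI,35,O,TRUE
BFI,36,E,FALSE
BFI,37,A,TRUE
BFI,38,C,FALSE
BFI,39,N,FALSE
BFI,40,O,FALSE
BFI,41,O,TRUE
BFI,42,A,FALSE
BFI,43,C,TRUE
BFI,44,O,FALSE
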