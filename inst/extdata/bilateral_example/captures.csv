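"individual_id","detector","trap_id","occasion","simultaneous"
"A",1,2,1,0
"A",1,1,2,0
"A",1,3,3,0
"A",1,1,4,0
"A",1,2,4,1
"A",1,3,4,0
"A",2,3,1,0
"A",2,1,3,0
"A",2,2,4,1
"B",1,1,1,1
"B",1,3,1,0
"B",1,3,2,0
"B",1,2,4,0
"B",2,1,1,1
"B",2,1,2,0
"B",2,3,3,0
"P1",1,1,1,0
"P1",1,2,3,0
"P1",1,1,4,0
"P2",2,2,1,0
"P2",2,1,3,0
"P2",2,3,3,0
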