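# rule base of the step fuzzy controller (consequent: +1 increase, 0 maintain, -1 decrease)
"rule","error","rate","consequent","weight"
1,"Negative","Zero",1,1
2,"Negative","Negative",1,1
3,"Any","Positive",0,1
4,"Positive","Any",-1,0.75
5,"Zero","Any",0,1
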