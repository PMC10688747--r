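"name","start","end","code"
"Early Horizon",-200,200,1
"Early Intermediate",200,650,2
"Middle Horizon",650,1000,3
"Late Intermediate",1000,1450,5
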