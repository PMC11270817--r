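{"format":"flowfe-system","version":1,"type":"toy","centers":[[0.25,0.25,0.25],[0.75,0.75,0.75],[0.25,0.75,0.25],[0.75,0.25,0.75],[0.25,0.25,0.75],[0.75,0.75,0.25]],"stiffness":[200,200,200,200,200,200],"depth":[0,1,0.5,0.5,2,0],"group":[1,1,2,2,3,3],"a":0,"b":1}
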