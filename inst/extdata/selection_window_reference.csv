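trait,window,mean_range
HD,5,16.7
HD,6,17.0
HD,7,17.3
LW,1,2.9
LW,2,3.1
LW,3,3.4
H,1,3.0
H,2,3.2
H,3,3.5
LC,1,2.3
LC,2,2.4
LC,3,2.3
GH,1,3.2
GH,2,3.3
GH,3,3.5
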