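name,x,y
AF3,-0.178,0.7799
F3,-0.4988,0.6255
F7,-0.7208,0.3471
FC5,-0.8,0
T7,-0.7208,-0.3471
P7,-0.4988,-0.6255
O1,-0.178,-0.7799
AF4,0.178,0.7799
F4,0.4988,0.6255
F8,0.7208,0.3471
FC6,0.8,0
T8,0.7208,-0.3471
P8,0.4988,-0.6255
O2,0.178,-0.7799
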