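quantity,phase,side,scheme,value
f1,one,,coarse3,0.8343
f1_sd,one,,coarse3,0.1362
f1,two,left,bins45,0.919
f1_sd,two,left,bins45,0.0736
f1,two,left,bins30,0.830
f1_sd,two,left,bins30,0.156
f1,two,left,bins15,0.786
f1_sd,two,left,bins15,0.174
accuracy,two,left,bins45,0.915
accuracy,two,left,bins30,0.847
accuracy,two,left,bins15,0.815
f1,two,right,bins45,0.900
f1_sd,two,right,bins45,0.133
f1,two,right,bins30,0.812
f1_sd,two,right,bins30,0.157
f1,two,right,bins15,0.740
f1_sd,two,right,bins15,0.188
accuracy,two,right,bins45,0.894
accuracy,two,right,bins30,0.823
accuracy,two,right,bins15,0.754
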