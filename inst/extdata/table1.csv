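stage,n_clones,min_fcm,avg_fcm,max_fcm
0,48,0.0,0.6,2.0
1,50,0.0,0.8,3.0
2,52,0.0,1.7,5.8
3,48,0.0,1.6,5.2
4,47,1.0,4.7,15.0
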