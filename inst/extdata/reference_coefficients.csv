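category,term,estimate,t_value
Athericidae,intercept,-4.965,-10.39
Athericidae,stream,1.354,2.33
Athericidae,species,2.474,4.77
Athericidae,species:stream,-3.053,-2.47
Baetidae,intercept,-1.356,-12.88
Baetidae,stream,-1.780,-5.18
Brachycentridae,intercept,-1.095,-6.55
Brachycentridae,stream,-0.855,-2.58
Brachycentridae,species,-1.815,-3.99
Chironomidae,intercept,1.642,1.74
Chironomidae,stream,-0.346,-1.17
Chironomidae,species,-2.860,-6.09
Chironomidae,length,-0.010,-3.15
Chironomidae,species:stream,2.645,3.47
Ephemerellidae,intercept,-1.635,-11.41
Ephemerellidae,stream,0.584,2.47
Heptageniidae,intercept,-3.614,-18.19
Heptageniidae,stream,-2.254,-2.39
Hydropsychidae,intercept,-3.535,-13.40
Hydropsychidae,stream,2.413,7.86
Oligochaeta,intercept,-9.441,-4.48
Oligochaeta,stream,-2.118,-2.19
Oligochaeta,species,4.267,4.90
Oligochaeta,length,0.015,2.53
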