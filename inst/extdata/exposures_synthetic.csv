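sample,s1,s2,s3,s4,s5,s6,s7
SYN001,0.038528,0.853601,0.011361,0.001315,0.044346,0.020595,0.030254
SYN002,0.002059,0.816735,0.032443,0.033984,0.037435,0.041676,0.035668
SYN003,0.009688,0.813125,0.043602,0.021799,0.029302,0.036496,0.045988
SYN004,0.051427,0.848924,0.029449,0.024048,0.015563,0.029788,0.000801
SYN005,0.045195,0.837738,0.04416,0.020562,0.041264,0.005699,0.005382
SYN006,0.033312,0.830311,0.044642,0.007446,0.041191,0.004077,0.039021
SYN007,0.036393,0.03902,0.022371,0.019197,0.855363,0.025179,0.002477
SYN008,0.005015,0.026042,0.015648,0.026572,0.91269,0.007569,0.006464
SYN009,0.039226,0.047739,0.001149,0.026206,0.830721,0.037701,0.017258
SYN010,0.004189,0.025205,0.038085,0.007867,0.878135,0.042426,0.004093
SYN011,0.022967,0.01518,0.032924,0.029741,0.878574,0.002452,0.018162
SYN012,0.03856,0.006153,0.045689,0.022654,0.797573,0.040947,0.048424
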