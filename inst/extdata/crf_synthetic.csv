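"conc","beta_central","beta_low","beta_high","c0"
0,0.012,0.006,0.018,5
10,0.009,0.0045,0.0135,5
20,0.0072,0.0036,0.0108,5
30,0.006,0.003,0.009,5
40,0.00514286,0.00257143,0.00771429,5
50,0.0045,0.00225,0.00675,5
60,0.004,0.002,0.006,5
70,0.0036,0.0018,0.0054,5
80,0.00327273,0.00163636,0.00490909,5
90,0.003,0.0015,0.0045,5
100,0.00276923,0.00138462,0.00415385,5
110,0.00257143,0.00128571,0.00385714,5
120,0.0024,0.0012,0.0036,5
130,0.00225,0.001125,0.003375,5
140,0.00211765,0.00105882,0.00317647,5
150,0.002,0.001,0.003,5
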