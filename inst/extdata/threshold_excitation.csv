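frequency_hz,ethrq_db
40,32.0
50,28.18
63,23.9
80,19.2
100,15.68
125,12.67
160,10.09
200,8.08
250,6.3
315,4.87
400,3.63
500,2.31
16000,2.31
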