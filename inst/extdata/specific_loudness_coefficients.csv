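g_db,alpha,a
-25,0.26692,12.0439
-20,0.25016,10.3019
-15,0.23679,8.6813
-10,0.22228,7.1868
-5,0.21055,5.8665
0,0.2,4.72096
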