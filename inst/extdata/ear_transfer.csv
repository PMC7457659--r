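frequency_hz,outer_db,middle_db
10,0.0,-50.0
20,0.0,-39.6
25,0.0,-32.0
31.5,0.0,-25.85
40,0.0,-21.4
50,0.0,-18.5
63,0.0,-15.9
80,0.0,-14.1
100,0.0,-12.4
125,0.1,-11.0
160,0.3,-9.6
200,0.5,-8.3
250,0.9,-7.4
315,1.4,-6.2
400,1.6,-4.8
500,1.7,-3.8
630,2.5,-3.3
750,2.7,-2.9
800,2.6,-2.6
1000,2.6,-2.6
1250,3.2,-4.5
1500,5.2,-5.4
1600,6.6,-6.1
2000,12.0,-8.5
2500,16.8,-10.4
3000,15.3,-7.3
3150,15.2,-7.0
4000,14.2,-6.6
5000,10.7,-7.0
6000,7.1,-9.2
6300,6.4,-10.2
8000,1.8,-12.2
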