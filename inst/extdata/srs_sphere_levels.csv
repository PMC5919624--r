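dose_pct,dose_gy,surface_area_mm2,volume_mm3,ddgi_mm,cdgi_mm
24,3.60,16497.6,165740.9,0.99,17.26
25,3.75,15268.0,150037.0,0.87,16.27
26,3.90,14272.0,137215.8,0.78,15.40
27,4.05,13438.1,126401.9,0.73,14.62
28,4.20,12682.9,116848.6,0.65,13.89
29,4.35,12016.5,108844.4,0.58,13.24
30,4.50,11416.7,102008.5,0.57,12.66
50,7.50,6187.0,44735.6,0.18,5.98
90,13.50,3722.9,21025.7,0.10,1.13
91,13.65,3677.5,20655.6,0.11,1.03
92,13.80,3628.4,20248.4,0.10,0.92
93,13.95,3586.0,19887.5,0.11,0.82
94,14.10,3537.9,19486.2,0.11,0.71
95,14.25,3490.1,19088.6,0.10,0.60
96,14.40,3444.6,18728.2,0.11,0.50
97,14.55,3397.9,18335.1,0.11,0.39
98,14.70,3346.7,17949.4,0.13,0.28
99,14.85,3293.4,17515.5,0.15,0.15
100,15.00,3235.7,17035.3,0.13,0.00
101,15.15,3180.6,16606.7,0.15,NA
102,15.30,3124.0,16144.7,0.13,NA
103,15.45,3068.3,15731.0,0.15,NA
104,15.60,3009.2,15284.3,0.16,NA
105,15.75,2944.0,14801.0,0.18,NA
106,15.90,2876.2,14290.8,0.20,NA
107,16.05,2804.1,13719.9,0.18,NA
108,16.20,2732.5,13226.9,0.23,NA
109,16.35,2648.1,12608.6,0.25,NA
110,16.50,2556.7,11946.2,0.25,NA
111,16.65,2464.2,11308.0,0.31,NA
112,16.80,2356.9,10557.6,0.33,NA
113,16.95,2241.2,9804.0,0.39,NA
114,17.10,2109.2,8944.8,0.46,NA
115,17.25,1960.4,8005.2,0.54,NA
116,17.40,1792.9,6993.9,0.68,NA
117,17.55,1594.9,5837.9,0.83,NA
118,17.70,1365.5,4612.7,1.15,NA
119,17.85,1077.1,3207.2,1.60,NA
120,18.00,731.1,1763.2,2.29,NA
121,18.15,341.0,536.3,NA,NA
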