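ptv_index,plan_id,target_id,v_ptv_cc,d_ptv_cm,sa_ptv_cm2,prescription_gy,dn_pct,r50_clinical,r50_analytic_gk,difference
1A,1,A,0.886,1.19,4.66,20,98.5,3.29,2.53,0.76
2A,2,A,0.091,0.56,1.09,22,99.5,8.45,7.87,0.58
2B,2,B,0.080,0.53,1.01,22,100.0,9.56,8.93,0.63
2C,2,C,0.039,0.42,0.61,22,100.0,15.03,17.37,-2.35
3A,3,A,1.378,1.38,6.68,20,98.0,3.61,2.72,0.89
4A,4,A,0.113,0.60,1.16,22,99.2,7.21,6.06,1.16
4D,4,D,0.480,0.97,3.18,20,99.5,5.66,2.56,3.11
4G,4,G,0.011,0.28,0.21,22,100.0,44.00,49.30,-5.30
5A,5,A,0.750,1.13,4.13,20,97.5,3.77,2.43,1.33
6A,6,A,27.394,3.74,52.34,30,98.6,2.67,2.95,-0.28
7A,7,A,3.830,1.94,14.6,18,99.8,3.74,2.95,0.79
7B,7,B,0.048,0.45,0.67,22,100.0,14.79,13.61,1.18
8A,8,A,0.385,0.90,3.1,20,99.4,3.89,2.97,0.92
9A,9,A,10.352,2.70,25.09,27,98.0,2.96,2.76,0.20
10A,10,A,0.252,0.78,2.06,20,99.6,3.93,3.40,0.53
11A,11,A,9.534,2.63,23.75,27,98.7,3.05,2.76,0.29
11B,11,B,0.104,0.58,1.09,27,98.6,5.46,6.47,-1.01
12C,12,C,1.486,1.42,7.47,18,100.0,3.77,2.83,0.94
13A,13,A,7.917,2.47,20.61,18,98.2,2.92,2.72,0.20
14A,14,A,1.576,1.44,6.66,20,98.4,3.07,2.57,0.49
15A,15,A,7.895,2.47,20.52,27,99.1,3.09,2.72,0.37
15B,15,B,1.256,1.34,6.77,27,98.2,5.27,2.85,2.42
16A,16,A,11.971,2.84,31.37,27,98.2,2.75,3.00,-0.25
17C,17,C,8.077,2.49,20.78,30,95.9,3.39,2.72,0.67
17D,17,D,0.112,0.60,1.14,30,99.8,12.17,6.05,6.12
18A,18,A,1.464,1.41,6.77,20,99.7,3.77,2.68,1.09
18B,18,B,0.128,0.63,1.29,20,100.0,6.88,5.55,1.32
18C,18,C,0.244,0.78,2.24,20,98.5,12.28,3.74,8.54
18D,18,D,0.099,0.57,1.11,20,100.0,9.19,7.06,2.13
18E,18,E,0.022,0.35,0.45,20,100.0,37.36,33.01,4.35
18F,18,F,0.119,0.61,1.29,20,99.8,9.64,6.15,3.49
18G,18,G,0.361,0.88,2.6,20,99.9,9.81,2.80,7.01
18H,18,H,0.123,0.62,1.32,20,100.0,8.46,5.98,2.47
18I,18,I,0.711,1.11,4.07,20,99.8,6.42,2.45,3.97
18J,18,J,0.089,0.55,1.28,20,96.0,12.18,9.38,2.80
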