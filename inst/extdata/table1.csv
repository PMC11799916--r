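v_ptv_cc,delta_r_measured_cm,delta_r_fit_low_cm,delta_r_fit_high_cm
0.001,0.49,0.467,
0.10,0.26,0.252,
0.19,0.19,0.206,
0.55,0.18,0.171,
0.99,0.22,0.227,
1.00,,0.229,0.224
1.94,0.29,,0.284
2.94,0.31,,0.329
3.95,0.33,,0.365
6.91,0.43,,0.444
20.41,0.63,,0.644
44.91,0.83,,0.844
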