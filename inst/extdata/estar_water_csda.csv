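energy_keV,range_g_cm2
10,2.515e-4
100,1.431e-2
500,1.766e-1
1000,4.367e-1
2000,9.785e-1
3000,1.514e0
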