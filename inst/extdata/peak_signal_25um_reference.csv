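iodixanol_pct,mean_peak_signal,sd_peak_signal,n
0,0.1854,0.070,10
30,0.2566,0.07,10
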