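class,surface_ha,frequency_pct
wood,30.3,55.8
shrub,14.1,26.0
grasslands,3.7,6.9
rock,5.5,10.0
feedwater,0.7,1.3
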