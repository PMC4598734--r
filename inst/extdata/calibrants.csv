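protein,z,mass,ccs_ref
ubiquitin,9,8565.0,1960
ubiquitin,10,8565.0,2060
ubiquitin,11,8565.0,2130
myoglobin,15,16951.5,3320
myoglobin,16,16951.5,3410
myoglobin,17,16951.5,3480
myoglobin,18,16951.5,3560
myoglobin,19,16951.5,3630
myoglobin,20,16951.5,3700
myoglobin,21,16951.5,3770
myoglobin,22,16951.5,3830
cytochrome_c,11,12359.9,2300
cytochrome_c,12,12359.9,2390
cytochrome_c,13,12359.9,2470
cytochrome_c,14,12359.9,2550
cytochrome_c,15,12359.9,2610
cytochrome_c,16,12359.9,2670
cytochrome_c,17,12359.9,2720
cytochrome_c,18,12359.9,2770
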