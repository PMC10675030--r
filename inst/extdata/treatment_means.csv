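treatment,lai,eta,gy,eta_gf,eta_veg,wp
full_irrigation,7.22,268.3,10323.9,97.2,171.1,3.8
rainfed,5.81,218.1,7453.3,46.4,171.7,3.3
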