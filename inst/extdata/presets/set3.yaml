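# Phase-B calibration preset "set 3": doubled mate readiness, very wide
# litters (10 +/- 4), 70-day initial mating delay.
mate_readiness: 0.02
litter_mean: 10
litter_sd: 4
p_male: 0.52
zone_mode: none
initial_delay: 70
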