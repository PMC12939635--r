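# Phase-B calibration preset "set 1": narrow Gaussian litters around 10 pups,
# male-biased sex ratio, 60-day initial mating delay.
mate_readiness: 0.01
litter_mean: 10
litter_sd: 1
p_male: 0.54
zone_mode: none
initial_delay: 60
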