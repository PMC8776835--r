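key,value
vial_id,enrichment
total_volume,120
liquid_volume,50
temperature,293.15
headspace_pressure,101325
sampling_fraction,0.01
stirred,TRUE
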