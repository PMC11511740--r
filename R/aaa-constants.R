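# shared unit-conversion constants (loaded first)

# 1 mmHg in Pa
.MMHG_PA <- 133.322387415

# volumetric flow conversion: m^3/s -> ml/min
.M3S_MLMIN <- 6e7
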