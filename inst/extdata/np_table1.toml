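# Nucleus pulposus, compressible Mooney-Rivlin (literature values).
# Bulk modulus corresponds to Poisson's ratio 0.495.
[material]
tissue = "np"
units = "kPa"
b10 = 0.12
b01 = 0.03
k = 29.9
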