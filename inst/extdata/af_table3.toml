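# Annulus fibrosus, parameters calibrated by inverse FEM against mean
# cadaveric range-of-motion curves of non-degenerated segments.
[material]
tissue = "af"
units = "kPa"
c10 = 0.016
c01 = 0.001
a1 = 1.0
a2 = 151.0
k = 170.0
phi = 30.0
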