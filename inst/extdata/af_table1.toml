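# Annulus fibrosus, fiber-reinforced Mooney-Rivlin (literature values).
# Bulk modulus corresponds to Poisson's ratio 0.45; fibers at +/-30 degrees.
[material]
tissue = "af"
units = "kPa"
c10 = 0.18
c01 = 0.045
a1 = 2.0
a2 = 100.0
k = 4.35
phi = 30.0
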