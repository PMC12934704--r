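# Bead-peptide statistical geometry library (synthetic toy chemistry).
# One record per line; units Angstrom / degrees; sigma is the spread of the
# harmonic statistical potential. "+NAME" marks an atom of the next residue.
residue BEA
bond BEA N CA 1.460 0.020
bond BEA CA C 1.520 0.020
bond BEA CA CB 1.530 0.020
angle BEA N CA C 110.0 2.0
angle BEA N CA CB 110.0 2.5
angle BEA C CA CB 108.9 2.5
link bond C +N 1.330 0.020
link angle CA C +N 116.0 2.0
link angle C +N +CA 122.0 1.8
link ss SG SG 2.033 0.016
default angle 109.5 3.0
vdw C 1.70
vdw N 1.55
vdw O 1.52
vdw S 1.80
vdw H 1.20
vdw P 1.80
nonbond cutoff 5.0
clash margin 0.4
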