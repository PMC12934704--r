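# Coarse amino-acid statistical geometry library.
# Backbone values follow standard protein restraint dictionaries; side-chain
# bond lengths are approximate element/context averages with loose sigmas.
# Intended for topology inference and coarse scoring of real residues; the
# bead library is the reference chemistry for synthetic fixtures.
residue ALA
residue ARG
residue ASN
residue ASP
residue CYS
residue GLN
residue GLU
residue GLY
residue HIS
residue ILE
residue LEU
residue LYS
residue MET
residue PHE
residue PRO
residue SER
residue THR
residue TRP
residue TYR
residue VAL
residue HOH
bond * N CA 1.458 0.019
bond * CA C 1.525 0.021
bond * C O 1.231 0.020
bond * C OXT 1.231 0.020
bond * CA CB 1.530 0.020
angle * N CA C 111.0 2.7
angle * CA C O 120.8 1.7
angle * CA C OXT 117.0 2.0
angle * N CA CB 110.4 1.8
angle * C CA CB 110.5 1.8
link bond C +N 1.329 0.014
link angle CA C +N 116.2 2.0
link angle C +N +CA 121.7 1.8
link angle O C +N 123.0 1.6
link ss SG SG 2.033 0.016
bond ARG CB CG 1.520 0.030
bond ARG CG CD 1.520 0.030
bond ARG CD NE 1.460 0.030
bond ARG NE CZ 1.330 0.030
bond ARG CZ NH1 1.330 0.030
bond ARG CZ NH2 1.330 0.030
bond ASN CB CG 1.516 0.025
bond ASN CG OD1 1.231 0.020
bond ASN CG ND2 1.328 0.021
bond ASP CB CG 1.516 0.025
bond ASP CG OD1 1.249 0.019
bond ASP CG OD2 1.249 0.019
bond CYS CB SG 1.808 0.033
bond GLN CB CG 1.520 0.030
bond GLN CG CD 1.516 0.025
bond GLN CD OE1 1.231 0.020
bond GLN CD NE2 1.328 0.021
bond GLU CB CG 1.520 0.030
bond GLU CG CD 1.516 0.025
bond GLU CD OE1 1.249 0.019
bond GLU CD OE2 1.249 0.019
bond HIS CB CG 1.497 0.014
bond HIS CG ND1 1.371 0.017
bond HIS ND1 CE1 1.319 0.013
bond HIS CE1 NE2 1.374 0.011
bond HIS NE2 CD2 1.374 0.011
bond HIS CD2 CG 1.356 0.011
bond ILE CB CG1 1.530 0.020
bond ILE CB CG2 1.521 0.033
bond ILE CG1 CD1 1.513 0.039
bond LEU CB CG 1.530 0.020
bond LEU CG CD1 1.521 0.033
bond LEU CG CD2 1.521 0.033
bond LYS CB CG 1.520 0.030
bond LYS CG CD 1.520 0.030
bond LYS CD CE 1.520 0.030
bond LYS CE NZ 1.489 0.030
bond MET CB CG 1.520 0.030
bond MET CG SD 1.803 0.034
bond MET SD CE 1.791 0.059
bond PHE CB CG 1.502 0.023
bond PHE CG CD1 1.384 0.021
bond PHE CD1 CE1 1.382 0.030
bond PHE CE1 CZ 1.382 0.030
bond PHE CZ CE2 1.382 0.030
bond PHE CE2 CD2 1.382 0.030
bond PHE CD2 CG 1.384 0.021
bond PRO CB CG 1.492 0.050
bond PRO CG CD 1.503 0.034
bond PRO CD N 1.473 0.014
bond SER CB OG 1.417 0.020
bond THR CB OG1 1.433 0.016
bond THR CB CG2 1.521 0.033
bond TRP CB CG 1.498 0.031
bond TRP CG CD1 1.365 0.025
bond TRP CD1 NE1 1.374 0.021
bond TRP NE1 CE2 1.370 0.011
bond TRP CE2 CD2 1.409 0.012
bond TRP CD2 CG 1.434 0.015
bond TRP CE2 CZ2 1.398 0.011
bond TRP CZ2 CH2 1.368 0.035
bond TRP CH2 CZ3 1.395 0.036
bond TRP CZ3 CE3 1.382 0.030
bond TRP CE3 CD2 1.398 0.011
bond TYR CB CG 1.512 0.015
bond TYR CG CD1 1.387 0.013
bond TYR CD1 CE1 1.389 0.015
bond TYR CE1 CZ 1.381 0.013
bond TYR CZ CE2 1.381 0.013
bond TYR CE2 CD2 1.389 0.015
bond TYR CD2 CG 1.387 0.013
bond TYR CZ OH 1.376 0.021
bond VAL CB CG1 1.521 0.033
bond VAL CB CG2 1.521 0.033
bond HOH O H1 0.960 0.020
bond HOH O H2 0.960 0.020
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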