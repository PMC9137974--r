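movement,trajectory,cx,cy,cz,nx,ny,nz,radius_cm
plantar_dorsiflexion,A,0.08649,2.138,-6.712,-0.089,-0.95,0.31,7.666
plantar_dorsiflexion,B,0.5713,5.531,-7.824,-0.089,-0.95,0.31,5.246
plantar_dorsiflexion,C,-0.2442,-2.669,-5.315,-0.089,-0.95,0.31,7.206
plantar_dorsiflexion,PM,0.1552,1.642,-6.683,-0.089,-0.95,0.31,5.375
inversion_eversion,A,4.444,1.825,-9.008,-0.75,-0.28,0.60,2.428
inversion_eversion,B,1.757,0.6768,-6.925,-0.75,-0.28,0.60,6.567
inversion_eversion,C,0.1578,0.1819,-5.807,-0.75,-0.28,0.60,6.935
inversion_eversion,PM,2.087,0.8882,-7.281,-0.75,-0.28,0.60,3.875
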