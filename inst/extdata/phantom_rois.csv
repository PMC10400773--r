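label,hemisphere,x_mm,y_mm,z_mm,radius_mm
projection,L,10,10,15,5
projection,R,35,10,15,5
association,L,10,35,15,5
association,R,35,35,15,5
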