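design,h_bl_pct,h_h_pct,r2_pct,radial_gap_mm,beta_2B_deg,addressed_effect,coupled_parameters
B,100,100,100,0.65,90,base design,
BH+,116,100,100,0.65,90,blade height,delta_sh
BH-,83,100,100,0.65,90,blade height,delta_sh
A60,100,100,100,0.65,60,blade angle,
RG+,100,100,95,1.15,90,diameter,omega;k_z
D-,100,100,100,1.15,90,radial gap,k_z
SO,100,100,136,0.65,90,long blades,shroud
HH-,100,80,100,0.65,90,hub area,k_z;delta_h
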