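design,mean_nih_mg_dl,std_nih_mg_dl,mean_nih_norm,std_nih_norm,speed_rpm,efficiency_pct
B,0.0096,0.0043,0.625,0.161,7880,40.1
BH+,0.0081,0.0151,0.605,0.180,7780,39.6
BH-,0.0180,0.0215,0.948,0.305,8060,37.1
A60,0.0106,0.0042,0.978,0.439,8050,40.1
D-,0.0059,0.0025,0.500,0.207,8330,40.5
RG+,0.0131,0.0142,0.458,0.140,7820,40.3
SO,0.0239,0.0329,0.933,0.342,5640,37.1
HH-,0.0130,0.0058,0.850,0.289,7920,41.3
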