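pump,nih_mg_dl,std_mg_dl,p,n,priming_volume_ml,speed_rpm
B,0.0096,0.0043,NA,16,15.5,7900
BPX-80,0.0502,0.0422,0.001,14,80,3140
FloPump 32,0.0261,0.0141,0.058,5,32,3830
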