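measurement,method,n,mean_mm,sd_mm,min_mm,max_mm
sc,2D,22,2.63,0.21,2.32,3.11
sc,3D,22,2.72,0.07,2.58,2.87
ti,2D,22,6.11,0.51,5.24,6.88
ti,3D,22,6.61,0.07,6.45,6.73
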