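trait,QMg,QMr,signif,CV_pct
PH,856.78,303.77,**,25.12
CD,0.78,0.86,ns,18.87
NR,0.30,0.10,**,8.54
FL,136.38,66.76,*,18.58
FD,30.45,20.66,ns,16.27
FFM,118.85,116.73,ns,54.76
NS,46075.81,23251.43,*,52.03
TSM,0.07,0.007,**,6.02
G,19.42,8.59,**,3.08
GSI,2.70,0.15,**,4.81
MGT,2.37,0.09,**,5.00
SL,0.08,0.01,**,8.13
SDM,0.08,0.01,**,11.74
DEN,0.04,0.01,**,14.45
SVI,544.28,78.64,**,7.32
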