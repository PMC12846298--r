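muscle,side,bias,loa_lower,loa_upper,pearson_r,icc_between,icc_intra_device,cv_device_pct,cv_reference_pct
PM,right,-0.03,-0.16,0.10,0.76,0.74,0.82,10.56,6.90
PM,left,-0.05,-0.25,0.15,0.21,0.17,0.20,9.91,8.43
AD,right,0.02,-0.06,0.09,0.93,0.92,0.92,0.92,7.59
AD,left,0.05,-0.11,0.21,0.71,0.64,0.64,8.58,6.76
MD,right,0.01,-0.11,0.13,0.79,0.80,0.78,9.67,8.45
MD,left,0.00,-0.16,0.17,0.82,0.79,0.72,10.20,7.21
PD,right,-0.03,-0.24,0.17,0.28,0.27,0.24,11.70,11.16
PD,left,-0.05,-0.23,0.13,0.41,0.34,0.41,10.60,8.82
UT,right,0.01,-0.09,0.12,0.35,0.36,0.41,6.25,6.78
UT,left,0.01,-0.14,0.15,0.53,0.55,0.64,8.10,7.27
LT,right,0.02,-0.17,0.21,0.30,0.31,0.29,8.77,8.41
LT,left,0.01,-0.19,0.20,0.56,0.54,0.58,12.17,9.59
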