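axis,side,bias,loa_lower,loa_upper,pearson_r,icc_between,icc_intra_device,cv_device_pct,cv_reference_pct
axis1,right,2.71,-6.53,11.94,0.70,0.62,0.83,7.20,7.98
axis2,right,-2.14,-16.98,12.69,0.18,0.19,0.42,14.23,10.12
axis3,right,5.71,-9.89,21.32,0.68,0.45,0.66,11.17,11.72
axis1,left,-3.01,-12.65,6.63,0.71,0.61,0.90,15.59,13.46
axis2,left,-4.75,-13.06,3.56,0.88,0.76,0.00,16.53,15.20
axis3,left,3.00,-8.09,14.09,0.75,0.67,0.86,17.75,16.56
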