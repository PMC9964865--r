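metric,method,model_1,model_2,model_3,model_4,model_5,average_printed,cam_printed
ssim,Landweber,0.5958,0.6597,0.5288,0.5767,0.5574,0.5837,24.26
ssim,CG,0.7985,0.587,0.6081,0.6905,0.581,0.653,11.07
ssim,NOSER,0.802,0.6365,0.6042,0.68,0.5929,0.6631,9.38
ssim,Newton-Raphson,0.8064,0.5174,0.6532,0.3932,0.5542,0.5849,24.01
ssim,ISTA,0.4397,0.6265,0.5055,0.5657,0.533,0.5341,35.8
ssim,FISTA,0.6857,0.6027,0.442,0.4566,0.4379,0.525,38.16
ssim,RS-FISTA,0.8188,0.7125,0.679,0.7166,0.6996,0.7253,NA
rmse,Landweber,6.2126,4.2844,5.9118,5.5837,5.202,5.4389,36.73
rmse,CG,2.3693,7.1053,4.579,3.8017,3.9482,4.3607,21.08
rmse,NOSER,2.3117,4.588,4.7049,3.7014,3.9506,3.8513,10.65
rmse,Newton-Raphson,2.4178,8.1639,4.0846,8.5454,4.0266,5.4477,36.83
rmse,ISTA,9.506,4.7078,6.1617,5.7965,5.7223,6.3789,46.05
rmse,FISTA,3.3496,5.0391,7.1245,7.6213,7.9063,6.2082,44.57
rmse,RS-FISTA,2.3031,3.6883,4.0452,3.5559,3.6139,3.4413,NA
psnr,Landweber,32.2653,35.4931,32.6965,33.1924,33.8074,33.4909,12.12
psnr,CG,40.6386,31.0991,34.9153,36.5313,36.2029,35.8774,4.66
psnr,NOSER,40.8521,34.8983,34.6797,36.7636,36.1975,36.6784,2.38
psnr,Newton-Raphson,40.4623,29.8928,35.9077,29.4961,36.032,34.3582,9.29
psnr,ISTA,28.5709,34.6745,32.3367,32.8675,32.9795,32.2858,16.31
psnr,FISTA,37.631,34.0838,31.0757,30.4902,30.1713,32.6904,14.87
psnr,RS-FISTA,40.8844,36.7942,35.992,37.1118,36.9713,37.5507,NA
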