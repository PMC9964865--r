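metric,method,model_1,model_2,model_3,model_4,model_5,model_6,model_7,model_8,model_9,model_10,average_printed,cam_printed
ssim,Landweber,0.6314,0.6560,0.4610,0.4755,0.6318,0.4950,0.5780,0.6106,0.5571,0.6958,0.5792,25.71
ssim,CG,0.7396,0.7060,0.6627,0.6503,0.5920,0.5912,0.6285,0.6054,0.6220,0.7377,0.6535,11.41
ssim,NOSER,0.8159,0.6872,0.6269,0.6481,0.6546,0.5969,0.6261,0.6311,0.6505,0.7533,0.6691,8.83
ssim,Newton-Raphson,0.8139,0.6885,0.6484,0.5559,0.4951,0.6009,0.5134,0.5920,0.4122,0.3751,0.5695,27.84
ssim,ISTA,0.5407,0.6064,0.4544,0.4734,0.4639,0.5068,0.5947,0.6011,0.4810,0.5506,0.5273,38.08
ssim,FISTA,0.6776,0.5293,0.4572,0.4707,0.6241,0.4898,0.4177,0.5998,0.5315,0.6617,0.5459,33.37
ssim,RS-FISTA,0.8642,0.8186,0.6824,0.7682,0.7002,0.6709,0.6467,0.6618,0.6629,0.8052,0.7281,NA
rmse,Landweber,4.1512,3.9204,9.5336,8.0922,4.7712,8.0247,5.0658,4.4982,5.9477,4.6288,5.8634,35.14
rmse,CG,2.2004,3.1769,3.3918,4.1313,5.5283,6.4158,4.3224,4.8471,4.7803,4.5498,4.3344,10.21
rmse,NOSER,3.0971,3.5265,3.9107,4.2672,4.4006,6.4183,4.2285,4.1526,4.5111,4.6980,4.3211,9.93
rmse,Newton-Raphson,3.0886,3.5107,3.2570,5.7159,7.5509,5.8777,5.9001,4.4714,8.8449,7.1195,5.5337,29.67
rmse,ISTA,3.5797,4.4090,9.6882,7.1962,7.7374,7.0151,4.6817,4.6917,7.3017,6.8406,6.3141,38.36
rmse,FISTA,3.5157,6.3535,9.6369,8.8076,4.8842,7.6574,8.5180,4.4623,6.4900,4.8457,6.5171,40.28
rmse,RS-FISTA,2.0716,3.1538,3.2188,4.1123,4.3155,4.8655,4.1900,4.0350,4.4323,4.5241,3.8919,NA
psnr,Landweber,35.76700003,36.2641,28.5456,29.9695,34.5583,30.0423,34.0379,35.0700,32.6438,35.4034,33.2302,10.16
psnr,CG,41.2807,38.0908,37.5221,35.8091,33.2789,31.9858,35.2599,34.4212,34.5417,34.971,35.7161,2.49
psnr,NOSER,38.3118,37.1838,36.2858,35.528,35.2607,31.9824,35.6071,35.7645,35.0451,34.6925,35.5662,2.92
psnr,Newton-Raphson,38.3356,37.2229,37.8745,32.9891,30.5708,32.7466,32.7137,35.1219,29.1969,31.0818,33.7854,8.35
psnr,ISTA,37.0539,35.2440,28.4059,30.9887,30.3589,31.2102,34.7228,34.7042,30.8623,31.429,32.4980,12.64
psnr,FISTA,37.2105,32.0705,28.4521,29.2336,34.3549,30.4492,29.5240,35.1396,31.8860,34.4236,32.2744,13.42
psnr,RS-FISTA,41.8048,38.1542,37.9769,35.8490,35.4301,34.3883,35.6865,36.0140,35.1982,35.5628,36.6065,NA
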