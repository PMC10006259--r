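trait,year,h2,kfold_mean,kfold_sd,forward_mean,forward_slope,pooled_mean
HD,2016,0.753,0.588,0.027,NA,NA,0.437
LW,2016,0.523,0.395,0.070,NA,NA,NA
H,2016,0.455,0.358,0.049,NA,NA,NA
LC,2016,0.348,0.250,0.037,NA,NA,NA
GH,2016,NA,NA,NA,NA,NA,NA
HD,2017,0.828,0.756,0.037,0.578,1.047,0.620
LW,2017,0.630,0.598,0.033,0.300,0.658,NA
H,2017,0.676,0.626,0.049,0.052,0.222,NA
LC,2017,NA,NA,NA,NA,NA,NA
GH,2017,0.605,0.560,0.023,NA,NA,NA
HD,2018,0.788,0.692,0.036,0.637,0.855,0.532
LW,2018,0.502,0.475,0.010,0.349,0.590,NA
H,2018,0.593,0.584,0.033,0.313,0.539,NA
LC,2018,NA,NA,NA,NA,NA,NA
GH,2018,0.583,0.513,0.022,0.354,0.547,NA
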