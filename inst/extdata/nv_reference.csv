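trait,occasion,h2,kfold_mean,kfold_sd
CP,MAY,0.429,0.474,0.049
WSC,MAY,0.294,0.303,0.030
IVVDMD,MAY,0.372,0.394,0.188
CP,AUG,0.284,0.258,0.100
WSC,AUG,0.385,0.312,0.037
IVVDMD,AUG,0.231,0.274,0.057
CP,SEP,0.325,0.226,0.065
WSC,SEP,0.352,0.345,0.066
IVVDMD,SEP,0.266,0.153,0.096
CP,NOV,0.214,0.184,0.107
WSC,NOV,0.201,0.041,0.079
IVVDMD,NOV,0.270,0.232,0.044
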