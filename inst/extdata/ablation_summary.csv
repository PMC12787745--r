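landmarc,gain,dtr,mean_error_m,sd_error_m,max_error_m,min_error_m
TRUE,FALSE,FALSE,0.455,0.264,0.921,0.422
TRUE,TRUE,FALSE,0.387,0.228,0.843,0.402
FALSE,FALSE,TRUE,0.099,0.135,0.187,0.054
FALSE,TRUE,TRUE,0.085,0.045,0.141,0.022
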