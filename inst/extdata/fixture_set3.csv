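site_id,in_pattern,map_present,cf_g,supra_reference
A2,FALSE,TRUE,11.57,FALSE
B2,TRUE,FALSE,NA,TRUE
B3,TRUE,FALSE,11,FALSE
C2,FALSE,TRUE,11.96,FALSE
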