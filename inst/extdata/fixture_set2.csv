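site_id,in_pattern,map_present,cf_g,supra_reference
A1,FALSE,TRUE,NA,FALSE
B2,TRUE,FALSE,8.9,FALSE
B3,TRUE,FALSE,NA,TRUE
C2,FALSE,TRUE,NA,FALSE
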