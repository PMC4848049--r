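site_id,in_pattern,map_present,cf_g,supra_reference
A4,TRUE,FALSE,NA,TRUE
B2,TRUE,FALSE,NA,TRUE
B3,TRUE,TRUE,7.3,FALSE
C1,TRUE,FALSE,NA,TRUE
C4,TRUE,FALSE,NA,TRUE
D1,FALSE,TRUE,8.9,FALSE
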