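site_id,in_pattern,map_present,cf_g,supra_reference
1,TRUE,FALSE,NA,TRUE
2,FALSE,TRUE,NA,FALSE
3,FALSE,TRUE,NA,FALSE
4,TRUE,FALSE,NA,TRUE
5,TRUE,FALSE,NA,TRUE
6,TRUE,FALSE,NA,TRUE
7,FALSE,TRUE,NA,FALSE
8,FALSE,TRUE,NA,FALSE
9,FALSE,TRUE,NA,FALSE
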