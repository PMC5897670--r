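"label","network","x","y","z"
"L Amy","reactivity",NA,NA,NA
"R Amy","reactivity",NA,NA,NA
"L midIns","reactivity",NA,NA,NA
"R midIns","reactivity",NA,NA,NA
"PAG","reactivity",NA,NA,NA
"dACC","reactivity",NA,NA,NA
"L IFG","regulation",NA,NA,NA
"R IFG","regulation",NA,NA,NA
"L MiFG","regulation",NA,NA,NA
"R MiFG","regulation",NA,NA,NA
"L SPL","regulation",NA,NA,NA
"R SPL","regulation",NA,NA,NA
"preSMA","regulation",NA,NA,NA
"vmPFC","regulation",NA,NA,NA
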