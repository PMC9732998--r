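"name","direction","scale","worst","best"
"cost","minimize","natural",NA,NA
"demand","maximize","natural",NA,NA
"lead_time","minimize","natural",NA,NA
"criticality","maximize","built",1,3
"volume","minimize","natural",NA,NA
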