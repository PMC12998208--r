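criterion,group,threshold,direction,unit
wc,male,102,ge,cm
wc,female,88,ge,cm
wc,male_asian,90,ge,cm
wc,female_asian,80,ge,cm
tg,all,1.7,ge,mmol/L
hdl,male,1.0,lt,mmol/L
hdl,female,1.3,lt,mmol/L
sbp,all,130,ge,mmHg
dbp,all,85,ge,mmHg
hba1c,all,5.7,ge,%
glu,all,5.6,ge,mmol/L
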