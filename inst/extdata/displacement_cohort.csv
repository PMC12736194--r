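id,group,displacement_norm_pct,nonzero,label
1b,fc,NA,TRUE,active
5b,fc,NA,TRUE,active
7b,fc,NA,TRUE,active
1c,fc,NA,TRUE,active
5c,fc,NA,TRUE,active
7c,fc,NA,TRUE,active
1d,fc,NA,TRUE,active
5d,fc,NA,TRUE,active
7d,fc,NA,TRUE,active
7a,fc,NA,TRUE,active
1a,fc,0,FALSE,inactive
1e,fc,0,FALSE,inactive
Fc,fc,0,FALSE,inactive
5a,fc,0,FALSE,inactive
5e,fc,0,FALSE,inactive
8,fc,0,FALSE,inactive
9,fc,0,FALSE,inactive
don,reference,100,TRUE,active
tac,reference,26,TRUE,inactive
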