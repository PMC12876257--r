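# Reference combined Accept/Neutral/Reject verdicts per modality pair and
# group, as published alongside the per-index tables in reference_decisions.csv.
group,mod_a,mod_b,verdict
Meditator,MED,MM,Reject
Meditator,MED,WORDS,Reject
Meditator,MED,SENT,Reject
Meditator,MED,IMG,Reject
Meditator,MED,VDO,Reject
Meditator,MM,WORDS,Accept
Meditator,MM,SENT,Neutral
Meditator,MM,IMG,Accept
Meditator,MM,VDO,Reject
Meditator,WORDS,SENT,Accept
Meditator,WORDS,IMG,Accept
Meditator,WORDS,VDO,Reject
Meditator,SENT,IMG,Reject
Meditator,SENT,VDO,Reject
Meditator,IMG,VDO,Reject
Non-Meditator,MED,MM,Reject
Non-Meditator,MED,WORDS,Reject
Non-Meditator,MED,SENT,Accept
Non-Meditator,MED,IMG,Reject
Non-Meditator,MED,VDO,Reject
Non-Meditator,MM,WORDS,Accept
Non-Meditator,MM,SENT,Accept
Non-Meditator,MM,IMG,Accept
Non-Meditator,MM,VDO,Accept
Non-Meditator,WORDS,SENT,Accept
Non-Meditator,WORDS,IMG,Accept
Non-Meditator,WORDS,VDO,Reject
Non-Meditator,SENT,IMG,Accept
Non-Meditator,SENT,VDO,Neutral
Non-Meditator,IMG,VDO,Accept
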