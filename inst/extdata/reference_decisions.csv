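# Reference pairwise Welch-test outcomes (0 = accept H0, 1 = reject H0) per
# index (H, PSk, TP, DFs) and group, between six modalities, from a published
# 20-participant meditation study (11 meditators, 9 non-meditators).
# borderline marks cells reported as falling very close to alpha = 0.05.
index,group,mod_a,mod_b,decision,borderline
H,Meditator,MED,MM,1,FALSE
H,Meditator,MED,WORDS,1,FALSE
H,Meditator,MED,SENT,0,FALSE
H,Meditator,MED,IMG,1,FALSE
H,Meditator,MED,VDO,1,FALSE
H,Meditator,MM,WORDS,0,FALSE
H,Meditator,MM,SENT,1,FALSE
H,Meditator,MM,IMG,0,FALSE
H,Meditator,MM,VDO,1,FALSE
H,Meditator,WORDS,SENT,0,FALSE
H,Meditator,WORDS,IMG,0,FALSE
H,Meditator,WORDS,VDO,1,FALSE
H,Meditator,SENT,IMG,1,FALSE
H,Meditator,SENT,VDO,1,FALSE
H,Meditator,IMG,VDO,1,FALSE
H,Non-Meditator,MED,MM,1,FALSE
H,Non-Meditator,MED,WORDS,1,FALSE
H,Non-Meditator,MED,SENT,0,FALSE
H,Non-Meditator,MED,IMG,1,FALSE
H,Non-Meditator,MED,VDO,1,FALSE
H,Non-Meditator,MM,WORDS,0,FALSE
H,Non-Meditator,MM,SENT,0,FALSE
H,Non-Meditator,MM,IMG,0,FALSE
H,Non-Meditator,MM,VDO,0,FALSE
H,Non-Meditator,WORDS,SENT,0,FALSE
H,Non-Meditator,WORDS,IMG,0,FALSE
H,Non-Meditator,WORDS,VDO,1,FALSE
H,Non-Meditator,SENT,IMG,0,FALSE
H,Non-Meditator,SENT,VDO,1,FALSE
H,Non-Meditator,IMG,VDO,0,FALSE
PSk,Meditator,MED,MM,1,FALSE
PSk,Meditator,MED,WORDS,1,FALSE
PSk,Meditator,MED,SENT,1,TRUE
PSk,Meditator,MED,IMG,1,FALSE
PSk,Meditator,MED,VDO,1,FALSE
PSk,Meditator,MM,WORDS,0,FALSE
PSk,Meditator,MM,SENT,1,FALSE
PSk,Meditator,MM,IMG,0,FALSE
PSk,Meditator,MM,VDO,1,FALSE
PSk,Meditator,WORDS,SENT,1,FALSE
PSk,Meditator,WORDS,IMG,0,FALSE
PSk,Meditator,WORDS,VDO,1,FALSE
PSk,Meditator,SENT,IMG,1,FALSE
PSk,Meditator,SENT,VDO,1,FALSE
PSk,Meditator,IMG,VDO,1,FALSE
PSk,Non-Meditator,MED,MM,1,FALSE
PSk,Non-Meditator,MED,WORDS,1,FALSE
PSk,Non-Meditator,MED,SENT,0,FALSE
PSk,Non-Meditator,MED,IMG,1,FALSE
PSk,Non-Meditator,MED,VDO,1,FALSE
PSk,Non-Meditator,MM,WORDS,0,FALSE
PSk,Non-Meditator,MM,SENT,0,FALSE
PSk,Non-Meditator,MM,IMG,0,FALSE
PSk,Non-Meditator,MM,VDO,1,FALSE
PSk,Non-Meditator,WORDS,SENT,0,FALSE
PSk,Non-Meditator,WORDS,IMG,0,FALSE
PSk,Non-Meditator,WORDS,VDO,1,FALSE
PSk,Non-Meditator,SENT,IMG,1,FALSE
PSk,Non-Meditator,SENT,VDO,1,FALSE
PSk,Non-Meditator,IMG,VDO,0,FALSE
TP,Meditator,MED,MM,1,FALSE
TP,Meditator,MED,WORDS,1,FALSE
TP,Meditator,MED,SENT,1,FALSE
TP,Meditator,MED,IMG,1,FALSE
TP,Meditator,MED,VDO,1,FALSE
TP,Meditator,MM,WORDS,0,FALSE
TP,Meditator,MM,SENT,0,FALSE
TP,Meditator,MM,IMG,0,FALSE
TP,Meditator,MM,VDO,0,TRUE
TP,Meditator,WORDS,SENT,0,FALSE
TP,Meditator,WORDS,IMG,0,FALSE
TP,Meditator,WORDS,VDO,1,FALSE
TP,Meditator,SENT,IMG,1,FALSE
TP,Meditator,SENT,VDO,1,FALSE
TP,Meditator,IMG,VDO,0,FALSE
TP,Non-Meditator,MED,MM,0,FALSE
TP,Non-Meditator,MED,WORDS,0,FALSE
TP,Non-Meditator,MED,SENT,0,FALSE
TP,Non-Meditator,MED,IMG,0,FALSE
TP,Non-Meditator,MED,VDO,0,FALSE
TP,Non-Meditator,MM,WORDS,0,FALSE
TP,Non-Meditator,MM,SENT,0,FALSE
TP,Non-Meditator,MM,IMG,0,FALSE
TP,Non-Meditator,MM,VDO,0,FALSE
TP,Non-Meditator,WORDS,SENT,0,FALSE
TP,Non-Meditator,WORDS,IMG,1,FALSE
TP,Non-Meditator,WORDS,VDO,1,FALSE
TP,Non-Meditator,SENT,IMG,0,FALSE
TP,Non-Meditator,SENT,VDO,0,FALSE
TP,Non-Meditator,IMG,VDO,0,FALSE
DFs,Meditator,MED,MM,1,FALSE
DFs,Meditator,MED,WORDS,1,FALSE
DFs,Meditator,MED,SENT,1,FALSE
DFs,Meditator,MED,IMG,1,FALSE
DFs,Meditator,MED,VDO,1,FALSE
DFs,Meditator,MM,WORDS,0,FALSE
DFs,Meditator,MM,SENT,0,FALSE
DFs,Meditator,MM,IMG,0,FALSE
DFs,Meditator,MM,VDO,0,FALSE
DFs,Meditator,WORDS,SENT,0,FALSE
DFs,Meditator,WORDS,IMG,0,FALSE
DFs,Meditator,WORDS,VDO,1,FALSE
DFs,Meditator,SENT,IMG,0,FALSE
DFs,Meditator,SENT,VDO,1,FALSE
DFs,Meditator,IMG,VDO,1,FALSE
DFs,Non-Meditator,MED,MM,1,FALSE
DFs,Non-Meditator,MED,WORDS,1,FALSE
DFs,Non-Meditator,MED,SENT,1,FALSE
DFs,Non-Meditator,MED,IMG,1,FALSE
DFs,Non-Meditator,MED,VDO,1,FALSE
DFs,Non-Meditator,MM,WORDS,0,FALSE
DFs,Non-Meditator,MM,SENT,0,FALSE
DFs,Non-Meditator,MM,IMG,0,FALSE
DFs,Non-Meditator,MM,VDO,0,FALSE
DFs,Non-Meditator,WORDS,SENT,0,FALSE
DFs,Non-Meditator,WORDS,IMG,0,FALSE
DFs,Non-Meditator,WORDS,VDO,1,FALSE
DFs,Non-Meditator,SENT,IMG,0,FALSE
DFs,Non-Meditator,SENT,VDO,0,FALSE
DFs,Non-Meditator,IMG,VDO,0,FALSE
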