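condition_id,icd9_prefixes,label
DM,250,diabetes mellitus
HTN,401;402;403;404;405,hypertensive disease
CHF,428,congestive heart failure
CVD,430;431;432;433;434;435;436;437;438,cerebrovascular disease
COPD,490;491;492;494;496,chronic obstructive pulmonary disease
CKD,585;586,chronic kidney disease
CAD,410;411;412;413;414,coronary artery disease
DEM,290;294.1;331.0,dementia
ARTH,714;715,arthritis
ENTR,374,entropion and other eyelid disorders
PD,332,Parkinson disease
ANEM,280;281;285,anemia
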