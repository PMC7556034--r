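variety,SFA_pct,MUFA_pct,PUFA_pct
AR,8.54,70.69,20.6
TU,8.57,72.12,19.1
CO,8.18,75.11,16.52
TX,7.84,76.28,15.54
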