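name,L,a,b
AR,63.26,8.25,23.70
TU,64.78,8.25,23.56
CO,65.20,7.66,23.08
TX,64.26,7.60,23.85
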