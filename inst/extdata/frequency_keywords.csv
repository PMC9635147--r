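phrase,doses_per_day
MORNING AND NIGHT,2
THREE TIMES,3
FOUR TIMES,4
3 TIMES,3
4 TIMES,4
TWICE,2
ONCE,1
NOCTE,1
MANE,1
TDS,3
QDS,4
BD,2
OD,1
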