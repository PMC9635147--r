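ics_band,min_addons,max_addons,step
NONE,0,,0
LOW,0,0,1
LOW,1,1,2
LOW,2,,3
MEDIUM,0,1,4
MEDIUM,2,,4
HIGH;UNKNOWN,0,,4
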