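#name=WNT_ligands
#min_present=15
WNT1
WNT2
WNT2B
WNT3
WNT3A
WNT4
WNT5A
WNT5B
WNT6
WNT7A
WNT7B
WNT8A
WNT8B
WNT9A
WNT9B
WNT10A
WNT10B
WNT11
WNT16
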