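analyte_id,me_pct,rsd_me_pct,er_pct,rsd_er_pct,pe_pct_printed
PFBA,131,13,98,18,129
PFPeA,180,19,91,18,163
PFHxA,128,12,93,22,119
PFHpA,169,22,109,20,185
PFOA,156,12,96,2,149
PFNA,152,18,82,21,125
PFDA,178,21,98,23,175
PFUdA,162,8,102,18,165
PFDoA,149,17,96,22,144
PFTrDA,130,12,83,5,108
PFTeDA,171,19,76,7,131
PFHxDA,145,19,77,23,112
PFODA,193,16,89,15,171
L-PFBS,178,18,84,8,178
L-PFHxS,131,23,90,7,131
L-PFOS,127,21,92,16,116
L-PFDS,148,13,84,2,124
HFPO-DA,84,10,103,16,84
ADONA,142,8,90,19,128
9Cl-PF3ONS,169,9,99,20,167
11Cl-PF3OUdS,186,18,101,8,187
PF4OPeA,166,10,96,13,159
PF5OHxA,167,5,94,18,157
PFEESA,138,19,98,11,134
"3,6-OPFHpA",143,22,92,17,132
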