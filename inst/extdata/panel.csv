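"name","precursor_mz","fragment_mz","collision_energy","cone_voltage","rt_min","separation","quantifiable","notes"
"Nam",123,96,16,32,9.82,"acidic",TRUE,"strikingly membrane permeable; losses to supernatants possible"
"NA",124,53,26,32,8.35,"acidic",TRUE,""
"Cytidine",244,112,18,18,11.14,"alkaline",TRUE,""
"Uridine",245,113,16,18,11.5,"alkaline",TRUE,""
"NR",255,123,12,14,8.98,"acidic",TRUE,""
"NAR",256,124,13,14,10.33,"alkaline",TRUE,""
"Inosine",269,137,12,12,12.88,"alkaline",TRUE,""
"CMP",324,112,22,16,2.97,"alkaline",TRUE,""
"UMP",325,97,12,20,4.11,"alkaline",TRUE,""
"NMN",335,123,12,16,8.92,"alkaline",TRUE,""
"NAMN",336,124,12,18,4.2,"alkaline",TRUE,""
"IMP",349,137,22,14,9.65,"alkaline",TRUE,""
"ADP",428,136,26,30,10.43,"alkaline",TRUE,""
"ATP",508,410,16,30,10.51,"alkaline",TRUE,""
"ADPr",560,348,16,26,11.08,"alkaline",TRUE,""
"NAD",664,428,26,26,13.64,"alkaline",TRUE,""
"NAAD",665,428,24,24,11.89,"alkaline",TRUE,""
"NADH",666,649,20,26,12.98,"alkaline",TRUE,""
"NADP",744,604,18,26,12.01,"alkaline",TRUE,"may include oxidized NADPH; interpret with care"
"NADPH",745,729,48,28,12.5,"alkaline",FALSE,"monitored but not reported: cannot be reliably quantified (oxidation); assumed RT"
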