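"metabolite","standard_set","mass_offset","fragment_offset"
"Cytidine","C13_extract",5,5
"Uridine","C13_extract",5,5
"NR","C13_extract",5,5
"NAR","C13_extract",5,5
"Inosine","C13_extract",5,0
"CMP","C13_extract",5,0
"UMP","C13_extract",5,5
"NMN","C13_extract",5,0
"NAMN","C13_extract",5,0
"IMP","C13_extract",5,0
"ADP","C13_extract",5,0
"ATP","C13_extract",5,5
"ADPr","C13_extract",10,10
"NAD","C13_extract",10,10
"NAAD","C13_extract",10,10
"NADH","C13_extract",10,10
"NADP","C13_extract",10,10
"NADPH","C13_extract",10,10
"Nam","O18_vitamins",2,2
"NR","O18_vitamins",2,2
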