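"source","target","mechanism","fraction"
"NR","Nam","on_source_fragmentation",0.1
"NMN","Nam","on_source_fragmentation",0.1
"NAR","NA","on_source_fragmentation",0.1
"NAMN","NA","on_source_fragmentation",0.1
"Cytidine","Uridine","isotopologue_bleed",0.05
"Nam","NA","isotopologue_bleed",0.05
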