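study,water_source,gain_kg_per_day
Crawford,Cattle have direct access to a dam,0.46
Crawford,"Well, spring or river water in trough",0.46
Willms,Cattle have direct access to a dam,0.64
Willms,Water pumped into trough from fenced dam,0.66
Willms,"Well, spring or river water in trough",0.79
Lardner,Cattle have direct access to a dam,0.97
Lardner,Water pumped into trough from fenced dam,1.00
Lardner,"Untreated dam water aerated continuously, pumped into trough",1.06
Lardner,"Untreated dam water coagulated & chlorinated, pumped into trough",1.05
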