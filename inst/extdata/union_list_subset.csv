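"compound","cas","sml_mg_kg"
"Tri-n-butyl acetyl citrate","77-90-7",""
"Benzophenone","119-61-9","0.6"
"Butylated hydroxytoluene","128-37-0","3"
"Irganox 1076","2082-79-3","6"
"Dibutyl phthalate","84-74-2",""
"Bis(2-ethylhexyl) phthalate","117-81-7","1.5"
"Bis(2-ethylhexyl) terephthalate","6422-86-2","60"
"Butyl palmitate","111-06-8","-"
"Butyl stearate","123-95-5",""
"Diphenyl sulphone","127-63-9",""
"Bis(2-ethylhexyl) adipate","103-23-1","18"
"Irgafos 168","31570-04-4","-"
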