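"year","band","new_cases","source"
"2025","50-64",400200,"Table 1 row 2025"
"2025","65-74",160300,"Table 1 row 2025"
"2025","75-84",105400,"Table 1 row 2025"
"2025","85+",31100,"Table 1 row 2025"
"2025","Overall",696900,"Table 1 row 2025"
"2026","50-64",390800,"Table 1 row 2026"
"2026","65-74",158500,"Table 1 row 2026"
"2026","75-84",103000,"Table 1 row 2026"
"2026","85+",30100,"Table 1 row 2026"
"2026","Overall",682400,"Table 1 row 2026"
"2027","50-64",380700,"Table 1 row 2027"
"2027","65-74",158100,"Table 1 row 2027"
"2027","75-84",100300,"Table 1 row 2027"
"2027","85+",28900,"Table 1 row 2027"
"2027","Overall",667900,"Table 1 row 2027"
"2028","50-64",370200,"Table 1 row 2028"
"2028","65-74",158500,"Table 1 row 2028"
"2028","75-84",97300,"Table 1 row 2028"
"2028","85+",27800,"Table 1 row 2028"
"2028","Overall",653800,"Table 1 row 2028"
"2029","50-64",360200,"Table 1 row 2029"
"2029","65-74",159100,"Table 1 row 2029"
"2029","75-84",94300,"Table 1 row 2029"
"2029","85+",27400,"Table 1 row 2029"
"2029","Overall",641000,"Table 1 row 2029"
"2030","50-64",352800,"Table 1 row 2030"
"2030","65-74",159700,"Table 1 row 2030"
"2030","75-84",91500,"Table 1 row 2030"
"2030","85+",27400,"Table 1 row 2030"
"2030","Overall",631300,"Table 1 row 2030"
"2031","50-64",348400,"Table 1 row 2031"
"2031","65-74",160100,"Table 1 row 2031"
"2031","75-84",88800,"Table 1 row 2031"
"2031","85+",27300,"Table 1 row 2031"
"2031","Overall",624600,"Table 1 row 2031"
"2032","50-64",345100,"Table 1 row 2032"
"2032","65-74",160400,"Table 1 row 2032"
"2032","75-84",86500,"Table 1 row 2032"
"2032","85+",27100,"Table 1 row 2032"
"2032","Overall",619200,"Table 1 row 2032"
"2033","50-64",341900,"Table 1 row 2033"
"2033","65-74",160100,"Table 1 row 2033"
"2033","75-84",84200,"Table 1 row 2033"
"2033","85+",27900,"Table 1 row 2033"
"2033","Overall",614100,"Table 1 row 2033"
"2034","50-64",338700,"Table 1 row 2034"
"2034","65-74",159300,"Table 1 row 2034"
"2034","75-84",82400,"Table 1 row 2034"
"2034","85+",28800,"Table 1 row 2034"
"2034","Overall",609200,"Table 1 row 2034"
"2035","50-64",335800,"Table 1 row 2035"
"2035","65-74",158000,"Table 1 row 2035"
"2035","75-84",81600,"Table 1 row 2035"
"2035","85+",28800,"Table 1 row 2035"
"2035","Overall",604200,"Table 1 row 2035"
"2036","50-64",333300,"Table 1 row 2036"
"2036","65-74",156700,"Table 1 row 2036"
"2036","75-84",81400,"Table 1 row 2036"
"2036","85+",28300,"Table 1 row 2036"
"2036","Overall",599700,"Table 1 row 2036"
"2037","50-64",331500,"Table 1 row 2037"
"2037","65-74",155100,"Table 1 row 2037"
"2037","75-84",81900,"Table 1 row 2037"
"2037","85+",27600,"Table 1 row 2037"
"2037","Overall",596000,"Table 1 row 2037"
"2038","50-64",330100,"Table 1 row 2038"
"2038","65-74",152300,"Table 1 row 2038"
"2038","75-84",82800,"Table 1 row 2038"
"2038","85+",26900,"Table 1 row 2038"
"2038","Overall",592200,"Table 1 row 2038"
"2039","50-64",329900,"Table 1 row 2039"
"2039","65-74",148600,"Table 1 row 2039"
"2039","75-84",83800,"Table 1 row 2039"
"2039","85+",26300,"Table 1 row 2039"
"2039","Overall",588600,"Table 1 row 2039"
"2040","50-64",330400,"Table 1 row 2040"
"2040","65-74",144400,"Table 1 row 2040"
"2040","75-84",84700,"Table 1 row 2040"
"2040","85+",25900,"Table 1 row 2040"
"2040","Overall",585400,"Table 1 row 2040"
"Total","50-64",5620000,"Table 1 totals row (as printed)"
"Total","65-74",2509209,"Table 1 totals row (as printed)"
"Total","75-84",1429900,"Table 1 totals row (as printed)"
"Total","85+",447600,"Table 1 totals row (as printed)"
"Total","Overall",10006500,"Table 1 totals row (as printed)"
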