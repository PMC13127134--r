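"year","sector","group","cost_millions","source"
2025,"primary","fit",1430.9,"Table 3 row 2025"
2025,"primary","frail",8910,"Table 3 row 2025"
2025,"primary","total",10340.9,"Table 3 row 2025"
2025,"secondary_urgent","fit",3607.5,"Table 3 row 2025"
2025,"secondary_urgent","frail",36818.6,"Table 3 row 2025"
2025,"secondary_urgent","total",40426.1,"Table 3 row 2025"
2025,"total","fit",5038.4,"Table 3 row 2025"
2025,"total","frail",45728.6,"Table 3 row 2025"
2025,"total","total",50767,"Table 3 row 2025"
2026,"primary","fit",1401.4,"Table 3 row 2026"
2026,"primary","frail",9088.4,"Table 3 row 2026"
2026,"primary","total",10489.9,"Table 3 row 2026"
2026,"secondary_urgent","fit",3533.1,"Table 3 row 2026"
2026,"secondary_urgent","frail",37696,"Table 3 row 2026"
2026,"secondary_urgent","total",41229.1,"Table 3 row 2026"
2026,"total","fit",4934.6,"Table 3 row 2026"
2026,"total","frail",46784.4,"Table 3 row 2026"
2026,"total","total",51719,"Table 3 row 2026"
2027,"primary","fit",1373,"Table 3 row 2027"
2027,"primary","frail",9252.6,"Table 3 row 2027"
2027,"primary","total",10625.5,"Table 3 row 2027"
2027,"secondary_urgent","fit",3459.9,"Table 3 row 2027"
2027,"secondary_urgent","frail",38508.2,"Table 3 row 2027"
2027,"secondary_urgent","total",41968.1,"Table 3 row 2027"
2027,"total","fit",4832.9,"Table 3 row 2027"
2027,"total","frail",47760.8,"Table 3 row 2027"
2027,"total","total",52593.6,"Table 3 row 2027"
2028,"primary","fit",1345.2,"Table 3 row 2028"
2028,"primary","frail",9403.1,"Table 3 row 2028"
2028,"primary","total",10748.3,"Table 3 row 2028"
2028,"secondary_urgent","fit",3387.3,"Table 3 row 2028"
2028,"secondary_urgent","frail",39254.3,"Table 3 row 2028"
2028,"secondary_urgent","total",42641.7,"Table 3 row 2028"
2028,"total","fit",4732.5,"Table 3 row 2028"
2028,"total","frail",48657.4,"Table 3 row 2028"
2028,"total","total",53390,"Table 3 row 2028"
2029,"primary","fit",1318.3,"Table 3 row 2029"
2029,"primary","frail",9540.3,"Table 3 row 2029"
2029,"primary","total",10858.6,"Table 3 row 2029"
2029,"secondary_urgent","fit",3319.1,"Table 3 row 2029"
2029,"secondary_urgent","frail",39954,"Table 3 row 2029"
2029,"secondary_urgent","total",43273.1,"Table 3 row 2029"
2029,"total","fit",4637.4,"Table 3 row 2029"
2029,"total","frail",49494.3,"Table 3 row 2029"
2029,"total","total",54131.6,"Table 3 row 2029"
2030,"primary","fit",1295.5,"Table 3 row 2030"
2030,"primary","frail",9666.2,"Table 3 row 2030"
2030,"primary","total",10961.8,"Table 3 row 2030"
2030,"secondary_urgent","fit",3263.1,"Table 3 row 2030"
2030,"secondary_urgent","frail",40617.7,"Table 3 row 2030"
2030,"secondary_urgent","total",43880.7,"Table 3 row 2030"
2030,"total","fit",4558.6,"Table 3 row 2030"
2030,"total","frail",50283.9,"Table 3 row 2030"
2030,"total","total",54842.5,"Table 3 row 2030"
2031,"primary","fit",1280.9,"Table 3 row 2031"
2031,"primary","frail",9784.7,"Table 3 row 2031"
2031,"primary","total",11065.6,"Table 3 row 2031"
2031,"secondary_urgent","fit",3226.2,"Table 3 row 2031"
2031,"secondary_urgent","frail",41248.7,"Table 3 row 2031"
2031,"secondary_urgent","total",44474.9,"Table 3 row 2031"
2031,"total","fit",4507,"Table 3 row 2031"
2031,"total","frail",51033.4,"Table 3 row 2031"
2031,"total","total",55540.5,"Table 3 row 2031"
2032,"primary","fit",1270.7,"Table 3 row 2032"
2032,"primary","frail",9895.9,"Table 3 row 2032"
2032,"primary","total",11166.6,"Table 3 row 2032"
2032,"secondary_urgent","fit",3198.4,"Table 3 row 2032"
2032,"secondary_urgent","frail",41835.7,"Table 3 row 2032"
2032,"secondary_urgent","total",45034.1,"Table 3 row 2032"
2032,"total","fit",4469.1,"Table 3 row 2032"
2032,"total","frail",51731.7,"Table 3 row 2032"
2032,"total","total",56200.8,"Table 3 row 2032"
2033,"primary","fit",1260.8,"Table 3 row 2033"
2033,"primary","frail",9998.6,"Table 3 row 2033"
2033,"primary","total",11259.4,"Table 3 row 2033"
2033,"secondary_urgent","fit",3172.6,"Table 3 row 2033"
2033,"secondary_urgent","frail",42385.9,"Table 3 row 2033"
2033,"secondary_urgent","total",45558.5,"Table 3 row 2033"
2033,"total","fit",4433.4,"Table 3 row 2033"
2033,"total","frail",52384.5,"Table 3 row 2033"
2033,"total","total",56817.9,"Table 3 row 2033"
2034,"primary","fit",1250.5,"Table 3 row 2034"
2034,"primary","frail",10090.4,"Table 3 row 2034"
2034,"primary","total",11340.9,"Table 3 row 2034"
2034,"secondary_urgent","fit",3151.1,"Table 3 row 2034"
2034,"secondary_urgent","frail",42924.4,"Table 3 row 2034"
2034,"secondary_urgent","total",46075.5,"Table 3 row 2034"
2034,"total","fit",4401.5,"Table 3 row 2034"
2034,"total","frail",53014.9,"Table 3 row 2034"
2034,"total","total",57416.4,"Table 3 row 2034"
2035,"primary","fit",1240.5,"Table 3 row 2035"
2035,"primary","frail",10173.8,"Table 3 row 2035"
2035,"primary","total",11414.2,"Table 3 row 2035"
2035,"secondary_urgent","fit",3127.5,"Table 3 row 2035"
2035,"secondary_urgent","frail",43400,"Table 3 row 2035"
2035,"secondary_urgent","total",46527.3,"Table 3 row 2035"
2035,"total","fit",4367.9,"Table 3 row 2035"
2035,"total","frail",53573.6,"Table 3 row 2035"
2035,"total","total",57941.5,"Table 3 row 2035"
2036,"primary","fit",1229.8,"Table 3 row 2036"
2036,"primary","frail",10249.3,"Table 3 row 2036"
2036,"primary","total",11479,"Table 3 row 2036"
2036,"secondary_urgent","fit",3100.4,"Table 3 row 2036"
2036,"secondary_urgent","frail",43822.4,"Table 3 row 2036"
2036,"secondary_urgent","total",46922.8,"Table 3 row 2036"
2036,"total","fit",4330.2,"Table 3 row 2036"
2036,"total","frail",54071.7,"Table 3 row 2036"
2036,"total","total",58401.9,"Table 3 row 2036"
2037,"primary","fit",1222.1,"Table 3 row 2037"
2037,"primary","frail",10320.5,"Table 3 row 2037"
2037,"primary","total",11542.6,"Table 3 row 2037"
2037,"secondary_urgent","fit",3080.1,"Table 3 row 2037"
2037,"secondary_urgent","frail",44213.8,"Table 3 row 2037"
2037,"secondary_urgent","total",47293.9,"Table 3 row 2037"
2037,"total","fit",4302.2,"Table 3 row 2037"
2037,"total","frail",54534.3,"Table 3 row 2037"
2037,"total","total",58836.5,"Table 3 row 2037"
2038,"primary","fit",1214.2,"Table 3 row 2038"
2038,"primary","frail",10387,"Table 3 row 2038"
2038,"primary","total",11601.2,"Table 3 row 2038"
2038,"secondary_urgent","fit",3059.5,"Table 3 row 2038"
2038,"secondary_urgent","frail",44576.7,"Table 3 row 2038"
2038,"secondary_urgent","total",47636.2,"Table 3 row 2038"
2038,"total","fit",4273.7,"Table 3 row 2038"
2038,"total","frail",54963.7,"Table 3 row 2038"
2038,"total","total",59237.4,"Table 3 row 2038"
2039,"primary","fit",1205,"Table 3 row 2039"
2039,"primary","frail",10448.5,"Table 3 row 2039"
2039,"primary","total",11653.5,"Table 3 row 2039"
2039,"secondary_urgent","fit",3036.1,"Table 3 row 2039"
2039,"secondary_urgent","frail",44913.9,"Table 3 row 2039"
2039,"secondary_urgent","total",47950,"Table 3 row 2039"
2039,"total","fit",4241.1,"Table 3 row 2039"
2039,"total","frail",55362.3,"Table 3 row 2039"
2039,"total","total",59603.4,"Table 3 row 2039"
2040,"primary","fit",1197.9,"Table 3 row 2040"
2040,"primary","frail",10507.4,"Table 3 row 2040"
2040,"primary","total",11705.4,"Table 3 row 2040"
2040,"secondary_urgent","fit",3017.6,"Table 3 row 2040"
2040,"secondary_urgent","frail",45238.1,"Table 3 row 2040"
2040,"secondary_urgent","total",48255.6,"Table 3 row 2040"
2040,"total","fit",4215.5,"Table 3 row 2040"
2040,"total","frail",55745.5,"Table 3 row 2040"
2040,"total","total",59961,"Table 3 row 2040"
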