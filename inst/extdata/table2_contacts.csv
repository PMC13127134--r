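"year","sector","group","contacts_millions","source"
2025,"primary","fit",37.4,"Table 2 row 2025"
2025,"primary","frail",225.1,"Table 2 row 2025"
2025,"primary","total",262.5,"Table 2 row 2025"
2025,"secondary_urgent","fit",12.8,"Table 2 row 2025"
2025,"secondary_urgent","frail",94.3,"Table 2 row 2025"
2025,"secondary_urgent","total",107.1,"Table 2 row 2025"
2026,"primary","fit",36.7,"Table 2 row 2026"
2026,"primary","frail",229.5,"Table 2 row 2026"
2026,"primary","total",266.2,"Table 2 row 2026"
2026,"secondary_urgent","fit",12.6,"Table 2 row 2026"
2026,"secondary_urgent","frail",96.3,"Table 2 row 2026"
2026,"secondary_urgent","total",108.9,"Table 2 row 2026"
2027,"primary","fit",35.9,"Table 2 row 2027"
2027,"primary","frail",233.6,"Table 2 row 2027"
2027,"primary","total",269.5,"Table 2 row 2027"
2027,"secondary_urgent","fit",12.3,"Table 2 row 2027"
2027,"secondary_urgent","frail",98.2,"Table 2 row 2027"
2027,"secondary_urgent","total",110.5,"Table 2 row 2027"
2028,"primary","fit",35.2,"Table 2 row 2028"
2028,"primary","frail",237.4,"Table 2 row 2028"
2028,"primary","total",272.6,"Table 2 row 2028"
2028,"secondary_urgent","fit",12.1,"Table 2 row 2028"
2028,"secondary_urgent","frail",100,"Table 2 row 2028"
2028,"secondary_urgent","total",112.1,"Table 2 row 2028"
2029,"primary","fit",34.5,"Table 2 row 2029"
2029,"primary","frail",240.8,"Table 2 row 2029"
2029,"primary","total",275.3,"Table 2 row 2029"
2029,"secondary_urgent","fit",11.8,"Table 2 row 2029"
2029,"secondary_urgent","frail",101.6,"Table 2 row 2029"
2029,"secondary_urgent","total",113.4,"Table 2 row 2029"
2030,"primary","fit",33.9,"Table 2 row 2030"
2030,"primary","frail",243.8,"Table 2 row 2030"
2030,"primary","total",277.7,"Table 2 row 2030"
2030,"secondary_urgent","fit",11.6,"Table 2 row 2030"
2030,"secondary_urgent","frail",103.1,"Table 2 row 2030"
2030,"secondary_urgent","total",114.7,"Table 2 row 2030"
2031,"primary","fit",33.5,"Table 2 row 2031"
2031,"primary","frail",246.7,"Table 2 row 2031"
2031,"primary","total",280.2,"Table 2 row 2031"
2031,"secondary_urgent","fit",11.5,"Table 2 row 2031"
2031,"secondary_urgent","frail",104.4,"Table 2 row 2031"
2031,"secondary_urgent","total",115.9,"Table 2 row 2031"
2032,"primary","fit",33.2,"Table 2 row 2032"
2032,"primary","frail",249.4,"Table 2 row 2032"
2032,"primary","total",282.6,"Table 2 row 2032"
2032,"secondary_urgent","fit",11.4,"Table 2 row 2032"
2032,"secondary_urgent","frail",105.7,"Table 2 row 2032"
2032,"secondary_urgent","total",117.1,"Table 2 row 2032"
2033,"primary","fit",33,"Table 2 row 2033"
2033,"primary","frail",251.9,"Table 2 row 2033"
2033,"primary","total",284.9,"Table 2 row 2033"
2033,"secondary_urgent","fit",11.3,"Table 2 row 2033"
2033,"secondary_urgent","frail",106.8,"Table 2 row 2033"
2033,"secondary_urgent","total",118.1,"Table 2 row 2033"
2034,"primary","fit",32.7,"Table 2 row 2034"
2034,"primary","frail",254.1,"Table 2 row 2034"
2034,"primary","total",286.8,"Table 2 row 2034"
2034,"secondary_urgent","fit",11.2,"Table 2 row 2034"
2034,"secondary_urgent","frail",107.8,"Table 2 row 2034"
2034,"secondary_urgent","total",119,"Table 2 row 2034"
2035,"primary","fit",32.4,"Table 2 row 2035"
2035,"primary","frail",256.1,"Table 2 row 2035"
2035,"primary","total",288.5,"Table 2 row 2035"
2035,"secondary_urgent","fit",11.1,"Table 2 row 2035"
2035,"secondary_urgent","frail",108.7,"Table 2 row 2035"
2035,"secondary_urgent","total",119.8,"Table 2 row 2035"
2036,"primary","fit",32.2,"Table 2 row 2036"
2036,"primary","frail",257.9,"Table 2 row 2036"
2036,"primary","total",290.1,"Table 2 row 2036"
2036,"secondary_urgent","fit",11,"Table 2 row 2036"
2036,"secondary_urgent","frail",109.5,"Table 2 row 2036"
2036,"secondary_urgent","total",120.5,"Table 2 row 2036"
2037,"primary","fit",32,"Table 2 row 2037"
2037,"primary","frail",259.6,"Table 2 row 2037"
2037,"primary","total",291.6,"Table 2 row 2037"
2037,"secondary_urgent","fit",10.9,"Table 2 row 2037"
2037,"secondary_urgent","frail",110.3,"Table 2 row 2037"
2037,"secondary_urgent","total",121.2,"Table 2 row 2037"
2038,"primary","fit",31.8,"Table 2 row 2038"
2038,"primary","frail",261.3,"Table 2 row 2038"
2038,"primary","total",293.1,"Table 2 row 2038"
2038,"secondary_urgent","fit",10.9,"Table 2 row 2038"
2038,"secondary_urgent","frail",111.1,"Table 2 row 2038"
2038,"secondary_urgent","total",122,"Table 2 row 2038"
2039,"primary","fit",31.5,"Table 2 row 2039"
2039,"primary","frail",262.8,"Table 2 row 2039"
2039,"primary","total",294.3,"Table 2 row 2039"
2039,"secondary_urgent","fit",10.8,"Table 2 row 2039"
2039,"secondary_urgent","frail",111.8,"Table 2 row 2039"
2039,"secondary_urgent","total",122.6,"Table 2 row 2039"
2040,"primary","fit",31.3,"Table 2 row 2040"
2040,"primary","frail",264.2,"Table 2 row 2040"
2040,"primary","total",295.5,"Table 2 row 2040"
2040,"secondary_urgent","fit",10.7,"Table 2 row 2040"
2040,"secondary_urgent","frail",112.5,"Table 2 row 2040"
2040,"secondary_urgent","total",123.2,"Table 2 row 2040"
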