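participant,observed_jsd,p_perm,z
001,0.8321,0.0228,2.2763
002,0.723,0.4831,0.7014
003,0.8305,0.0036,2.9147
004,0.7644,0.3933,0.8537
005,0.7864,0.1287,1.5191
006,0.8326,0.0226,2.2793
007,0.8016,0.3568,0.9215
008,0.8173,0.0641,1.8514
009,0.7972,0.6688,0.4277
010,0.8183,0.5271,0.6325
011,0.7709,0.4274,0.7936
012,0.8176,0.1939,1.2991
013,0.8186,0.2591,1.1285
014,0.7509,0.416,0.8134
015,0.8021,0.3161,1.0026
016,0.7057,0.5075,0.6627
017,0.8029,0.3199,0.9947
018,0.8298,0.0264,2.2195
019,0.8309,0.0269,2.2128
020,0.8272,0.03,2.1702
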