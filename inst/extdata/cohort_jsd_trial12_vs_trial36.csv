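participant,observed_jsd,p_perm,z
001,0.8055,0.3724,0.8921
002,0.6119,0.8466,0.1935
003,0.4169,0.985,0.0188
004,0.4043,0.9645,0.0445
005,0.4633,0.9721,0.035
006,0.5681,0.7679,0.2951
007,0.4554,0.931,0.0866
008,0.4066,0.989,0.0138
009,0.8326,0.0112,2.5355
010,0.6235,0.8024,0.2502
011,0.3905,0.9668,0.0416
012,0.6548,0.7542,0.3131
013,0.7429,0.3663,0.9034
014,0.6653,0.6777,0.4157
015,0.7945,0.4672,0.727
016,0.3753,0.9754,0.0308
017,0.4596,0.8104,0.2399
018,0.3812,0.9785,0.027
019,0.4742,0.9174,0.1037
020,0.4269,0.9591,0.0512
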