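participant,observed_jsd,p_perm,z
001,0.3498,0.9868,0.0165
002,0.401,0.9683,0.0397
003,0.342,0.9973,0.0034
004,0.07,0.964,0.0451
005,0.0715,0.9685,0.0395
006,0.062,0.9693,0.0385
007,0.2415,0.9982,0.0022
008,0.4767,0.9278,0.0906
009,0.2129,0.9994,0.0008
010,0.2048,0.9849,0.019
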