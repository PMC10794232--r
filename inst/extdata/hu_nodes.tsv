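hu	density_kg_m3	sound_speed_m_s
0	1000	1482
100	1060	1546
2000	1900	3942.12
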