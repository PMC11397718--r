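no,progeny,parent1,parent2,parent1_status,parent2_status,progeny_label6,parent1_label6,parent2_label6,pd_progeny,pd_parent1,pd_parent2,reconstructed
1,M. 'Adams',M. baccata,unknown,measured,unknown,D2,D2,,5.0,4.0,,FALSE
2,M. 'Almey',M. baccata,M. pumila var. neidzwetzkyana,measured,measured,D2,D2,D3,3.0,4.0,2.0,FALSE
3,M. 'Brandywine',syn_parent_03,unknown,measured,unknown,B,D3,,1.0,2.0,,TRUE
4,M. 'Cardinal',syn_parent_04,unknown,measured,unknown,D2,D3,,1.0,2.0,,TRUE
5,M. 'Dolgo',syn_parent_05,unknown,measured,unknown,D3,D3,,2.0,1.0,,TRUE
6,M. 'Eleyi',syn_parent_06,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
7,M. 'Flame',M. pumila,unknown,measured,unknown,D3,D3,,0.5,3.0,,FALSE
8,M. 'Golden Hornet',M. mandshurica,M. sieboldii,measured,untested,D3,D3,,2.0,1.0,,FALSE
9,M. 'Hillier',M. floribunda,M. prunifolia,measured,measured,D3,D2,D1,1.0,4.5,0.11,FALSE
10,M. 'Hopa',M. baccata,M. pumila var. neidzwetzkyana,measured,measured,D3,D3,D3,4.5,4.0,2.0,FALSE
11,M. 'Klehm''s Improved Bechtel',M. ioensis,unknown,measured,unknown,D2,D1,,1.2,0.5,,FALSE
12,M. 'Lisa',M. ioensis,unknown,measured,unknown,D2,D1,,0.8,0.5,,FALSE
13,M. 'Liset',syn_parent_13,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
14,M. 'Makamik',M. pumila var. neidzwetzkyana,unknown,measured,unknown,D3,D3,,0.4,2.0,,FALSE
15,M. 'Prairie Rose',M. ioensis,unknown,measured,unknown,D2,D1,,0.6,0.5,,FALSE
16,M. 'Professor Sprenger',M. mandshurica,M. sieboldii,measured,untested,D3,D3,,1.5,1.0,,FALSE
17,M. 'Profusion',syn_parent_17,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
18,M. 'Purple Prince',syn_parent_18,unknown,measured,unknown,D3,D3,,2.0,1.0,,TRUE
19,M. 'Radiant',syn_parent_19,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
20,M. 'Red Jade',syn_parent_20,unknown,measured,unknown,D2,D3,,1.0,2.0,,TRUE
21,M. 'Red Splendor',syn_parent_21,unknown,measured,unknown,D3,D3,,2.0,1.0,,TRUE
22,M. 'Robinson',M. baccata,M. pumila,measured,measured,D3,D2,D3,0.2,4.0,3.0,FALSE
23,M. 'Royalty',syn_parent_23,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
24,M. 'Rudolph',M. baccata,unknown,measured,unknown,D3,D2,,0.3,4.0,,FALSE
25,M. 'Sparkler',syn_parent_25,unknown,measured,unknown,D3,D3,,1.0,2.0,,TRUE
26,M. 'Spring Snow',syn_parent_26,unknown,measured,unknown,D3,D3,,2.0,1.0,,TRUE
27,'Van Eseltine',syn_parent_27,unknown,measured,unknown,C,D3,,11.18,2.0,,TRUE
28,M. zumi 'Calocarpa',M. mandshurica,M. sieboldii,measured,untested,D3,D3,,3.2,1.0,,FALSE
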