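taxon_id,name,rank,section,group,subgroup,label6
sp01,Species 01,species,I,D,D3,D3
sp02,Species 02,species,II,D,D1,D1
sp03,Species 03,species,II,D,D1,D1
sp04,Species 04,species,II,A,,A
sp05,Species 05,species,III,D,D2,D2
sp06,Species 06,species,III,D,D2,D2
sp07,Species 07,species,III,D,D2,D2
sp08,Species 08,species,III,D,D3,D3
sp09,Species 09,species,III,A,,A
sp10,Species 10,species,III,A,,A
sp11,Species 11,species,IV,D,D2,D2
sp12,Species 12,species,IV,D,D2,D2
sp13,Species 13,species,IV,D,D3,D3
sp14,Species 14,species,V,D,D3,D3
sp15,Species 15,species,V,D,D3,D3
sp16,Species 16,species,V,D,D3,D3
sp17,Species 17,species,V,D,D3,D3
sp18,Species 18,species,V,D,D2,D2
sp19,Species 19,species,V,D,D2,D2
sp20,Species 20,species,V,D,D2,D2
sp21,Species 21,species,V,D,D1,D1
sp22,Species 22,species,V,D,D1,D1
sp23,Species 23,species,V,B,,B
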