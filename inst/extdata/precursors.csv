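id,role,formula,charge,site_count,counterion_id
A,triamine,C24H21N3,0,3,
B,triamine,C18H18N4,0,3,
1,aldehyde,C6H5NO,0,1,
2,aldehyde,C7H7NO,0,1,
3,aldehyde,C7H7NO,0,1,
4,aldehyde,C7H7NO,0,1,
NTf2,counterion,C2F6NO4S2,-1,0,
OTf,counterion,CF3O3S,-1,0,
BF4,counterion,BF4,-1,0,
Zn(NTf2)2,metal_salt,Zn,2,0,NTf2
Zn(OTf)2,metal_salt,Zn,2,0,OTf
Zn(BF4)2,metal_salt,Zn,2,0,BF4
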