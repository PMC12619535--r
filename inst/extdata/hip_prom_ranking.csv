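rank,prom,count
1,mHHS,71
2,iHOT-12,35
3,HOS-SSS,33
4,NAHS,27
5,HOS-ADL,27
6,HOOS,8
7,iHOT-33,7
8,WOMAC,4
9,HAGOS,4
10,HHS,2
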