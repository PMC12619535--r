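name,scale_min,scale_max,orientation,mcid,mcid_source,synonyms
mHHS,0,100,higher_better,9.5,"Nwachukwu BU 2018, doi:10.1016/j.arthro.2018.01.050","modified Harris Hip Score"
iHOT-12,0,100,higher_better,13.0,"Nwachukwu BU 2018, doi:10.1016/j.arthro.2018.01.050; Martin RL 2019, doi:10.1016/j.arthro.2018.09.028","iHOT12|International Hip Outcome Tool-12"
HOS-SSS,0,100,higher_better,12.1,"Nwachukwu BU 2018, doi:10.1016/j.arthro.2018.01.050","HOS-Sport|HOS-Sports|HOS Sports Subscale"
NAHS,0,100,higher_better,8.5,"Bloom DA 2022, doi:10.1007/s00167-021-06756-9","Non-Arthritic Hip Score"
HOS-ADL,0,100,higher_better,9.8,"Nwachukwu BU 2018, doi:10.1016/j.arthro.2018.01.050","HOS Activities of Daily Living Subscale"
iHOT-33,0,100,higher_better,10.7,"Nwachukwu BU 2018, doi:10.1016/j.arthro.2018.01.050","iHOT33|International Hip Outcome Tool-33"
HOOS,0,100,higher_better,,"no single published MCID adopted","Hip disability and Osteoarthritis Outcome Score"
WOMAC,0,96,higher_worse,,"no single published MCID adopted","Western Ontario and McMaster Universities Osteoarthritis Index"
HAGOS,0,100,higher_better,,"no single published MCID adopted","Copenhagen Hip and Groin Outcome Score"
HHS,0,100,higher_better,,"no single published MCID adopted","Harris Hip Score"
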