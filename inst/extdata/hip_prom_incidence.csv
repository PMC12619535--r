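study_id,prom
S001,mHHS
S002,iHOT-12
S003,iHOT-33
S003,HOS-SSS
S003,HOS-ADL
S004,mHHS
S005,iHOT-12
S005,mHHS
S005,HOS-SSS
S005,NAHS
S006,mHHS
S007,mHHS
S008,mHHS
S009,iHOT-12
S009,mHHS
S010,iHOT-12
S010,mHHS
S010,NAHS
S011,iHOT-12
S011,mHHS
S011,HOOS
S012,mHHS
S012,HOS-SSS
S012,HOS-ADL
S012,NAHS
S013,mHHS
S013,HOS-SSS
S013,NAHS
S014,mHHS
S015,mHHS
S016,mHHS
S016,HOS-SSS
S016,HOS-ADL
S016,WOMAC
S017,iHOT-12
S017,mHHS
S018,iHOT-12
S018,mHHS
S019,mHHS
S019,NAHS
S020,iHOT-12
S020,mHHS
S021,iHOT-12
S021,mHHS
S021,HOS-SSS
S021,HOS-ADL
S022,iHOT-12
S022,mHHS
S023,iHOT-12
S023,mHHS
S024,mHHS
S024,HOS-SSS
S024,NAHS
S025,iHOT-12
S025,mHHS
S025,HOS-SSS
S025,HOS-ADL
S026,mHHS
S027,iHOT-12
S027,mHHS
S027,HOS-SSS
S027,NAHS
S028,mHHS
S028,NAHS
S029,iHOT-12
S030,HAGOS
S031,iHOT-12
S031,mHHS
S031,HOS-SSS
S031,NAHS
S032,mHHS
S032,HOS-SSS
S032,NAHS
S033,mHHS
S034,HOOS
S035,mHHS
S035,iHOT-33
S035,HOS-SSS
S035,HOS-ADL
S036,mHHS
S036,HAGOS
S037,iHOT-12
S037,mHHS
S037,HOS-SSS
S037,HOS-ADL
S038,mHHS
S038,HOS-SSS
S038,HOS-ADL
S039,mHHS
S040,iHOT-33
S041,iHOT-12
S041,HOS-SSS
S041,HOS-ADL
S042,mHHS
S043,iHOT-12
S043,mHHS
S043,HOS-SSS
S043,HOS-ADL
S044,mHHS
S044,iHOT-33
S044,HOS-SSS
S044,HOS-ADL
S044,NAHS
S045,mHHS
S046,iHOT-12
S046,NAHS
S046,HOOS
S047,mHHS
S048,mHHS
S048,NAHS
S049,HOS-SSS
S049,HOS-ADL
S050,mHHS
S050,WOMAC
S051,mHHS
S051,HOS-SSS
S051,NAHS
S052,mHHS
S052,iHOT-33
S052,HOS-SSS
S052,HOS-ADL
S052,NAHS
S053,HOS-ADL
S053,NAHS
S053,HHS
S054,iHOT-12
S055,mHHS
S055,NAHS
S056,mHHS
S056,HOS-SSS
S056,HOS-ADL
S057,mHHS
S058,iHOT-12
S058,mHHS
S058,HOS-SSS
S058,HOS-ADL
S059,mHHS
S059,HOS-SSS
S059,HOS-ADL
S060,HOOS
S061,HOOS
S062,iHOT-12
S062,NAHS
S063,HOOS
S064,mHHS
S064,HOS-SSS
S064,NAHS
S065,iHOT-12
S065,HOS-SSS
S065,HOS-ADL
S066,mHHS
S067,mHHS
S067,WOMAC
S068,HOOS
S069,mHHS
S070,mHHS
S071,iHOT-12
S071,mHHS
S072,mHHS
S072,NAHS
S073,iHOT-12
S073,mHHS
S073,NAHS
S074,HOS-ADL
S075,HOS-SSS
S075,HOS-ADL
S076,mHHS
S076,HOS-SSS
S077,iHOT-12
S077,NAHS
S078,mHHS
S079,iHOT-12
S079,mHHS
S080,iHOT-12
S080,HAGOS
S081,iHOT-12
S081,mHHS
S081,NAHS
S082,iHOT-12
S082,HAGOS
S083,mHHS
S084,mHHS
S084,HOS-SSS
S084,HOS-ADL
S085,HHS
S086,iHOT-12
S087,mHHS
S087,iHOT-33
S087,HOS-SSS
S087,HOS-ADL
S088,iHOT-12
S088,mHHS
S088,HOS-ADL
S089,iHOT-12
S090,HOS-SSS
S090,HOS-ADL
S090,NAHS
S091,mHHS
S092,mHHS
S092,HOS-ADL
S092,WOMAC
S093,iHOT-12
S093,mHHS
S093,HOS-SSS
S093,NAHS
S094,NAHS
S095,HOOS
S096,mHHS
S097,iHOT-12
S097,mHHS
S097,NAHS
S098,mHHS
S098,iHOT-33
S099,HOS-SSS
S099,HOS-ADL
S100,mHHS
S100,HOS-SSS
S100,HOS-ADL
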