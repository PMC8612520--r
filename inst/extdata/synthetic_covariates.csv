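group_id,land_hunt,water_hunt,intra_group_conflict,intra_cultural_conflict,inter_cultural_conflict,social_stratification,time_focus
G01,present,present,absent,absent,present,absent,1900
G02,absent,present,present,present,present,absent,1900
G03,present,present,present,present,absent,present,1900
G04,absent,present,absent,absent,absent,absent,1900
G05,present,absent,absent,present,present,present,1900
G06,absent,absent,present,absent,absent,present,1900
G07,absent,present,present,present,present,absent,1900
G08,absent,present,missing,present,absent,missing,1900
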