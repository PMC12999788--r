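name,lit_it,rm_ms_A,width_half_ms_A,width_base_ms_A,rm_ms_B,width_half_ms_B,width_base_ms_B,rm_ms_C,width_half_ms_C,width_base_ms_C,wrapped_C
Benzaldehyde,942,54,373,634,16,335,570,174,106,180,FALSE
Limonene,1023,136,207,351,30,265,450,400,69,117,FALSE
Citronellol,1211,69,312,530,42,337,572,42,247,420,FALSE
Cinnamyl Alcohol,1275,24,316,538,13,469,797,41,314,534,FALSE
Eugenol,1335,26,391,665,36,366,622,17,331,562,FALSE
beta-Damascone (Z),1402,53,269,457,46,351,596,28,153,260,FALSE
Camphor,1410,53,265,450,35,314,533,58,141,239,FALSE
Isoeugenol (E),1424,28,358,608,31,364,619,32,330,561,FALSE
Coumarin,1441,15,439,746,20,500,850,1262,337,573,TRUE
alpha-Santalol,1660,46,260,442,53,367,624,27,236,401,FALSE
Benzyl Benzoate,1737,24,299,508,29,403,684,3,312,530,FALSE
Benzyl Cinnamate,2130,16,337,573,21,512,869,12,471,800,FALSE
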