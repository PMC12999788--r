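name,fid_A,ms_A,fid_B,ms70_B,ms12_B,fid_C,ms_C
Benzaldehyde,0.998,0.994,1.000,0.988,1.000,0.999,0.995
Limonene,0.996,0.990,1.000,0.999,0.999,1.000,0.996
Citronellol,0.998,0.993,1.000,0.998,0.999,0.999,0.996
Cinnamyl Alcohol,0.997,0.998,0.999,0.998,1.000,0.995,0.997
Eugenol,0.998,0.998,1.000,0.998,0.997,0.998,0.996
beta-Damascone (Z),0.998,0.991,0.999,0.998,0.999,0.999,0.995
Camphor,0.998,0.997,1.000,0.996,0.995,0.999,0.993
Isoeugenol (E),0.998,0.998,1.000,1.000,0.998,0.996,0.996
Coumarin,0.997,0.995,1.000,0.996,0.998,1.000,0.997
alpha-Santalol,0.996,0.994,0.998,0.999,1.000,0.997,0.999
Benzyl Benzoate,0.997,0.997,0.999,0.999,1.000,0.999,0.995
Benzyl Cinnamate,0.997,0.998,1.000,0.998,0.994,0.995,0.996
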