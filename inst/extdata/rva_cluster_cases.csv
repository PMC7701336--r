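case_id,V_RV_ED,EF_RV
2512949,133.13,0.6361
2628396,175.77,0.4391
3423847,140.50,0.6524
3713328,169.65,0.7159
3874816,183.96,0.5622
4366978,134.68,0.5253
4681487,139.82,0.5439
4710306,144.86,0.2969
5101726,145.93,0.4382
5319688,151.30,0.5193
5561149,180.48,0.4188
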