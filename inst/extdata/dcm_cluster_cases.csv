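case_id,V_LV_ED,EF_LV,gt_V_LV_ED,gt_EF_LV
2432774,189.28,0.1974,208.24,0.20
3378112,213.28,0.1875,213.03,0.15
4879002,133.09,0.2703,144.59,0.29
5618713,192.87,0.2674,192.43,0.27
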