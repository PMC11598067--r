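bunch_id,n_total,r_mean_total_mm,r_sd_total_mm,n_visible_1,n_visible_2,n_visible_3,r_mean_px_1,r_mean_px_2,r_mean_px_3
Bunch_01,47,10.1,0.35,30,28,26,25,23,21
Bunch_02,52,9.3,0.52,37,32,41,21,21,19
Bunch_03,36,9.3,0.44,21,25,24,24,23,19
Bunch_04,39,9.2,0.59,23,23,21,25,22,19
Bunch_05,55,9.5,0.57,31,31,27,24,23,22
Bunch_06,51,10.1,0.36,32,35,29,23,22,25
Bunch_07,63,9.8,0.42,33,39,34,22,21,22
Bunch_08,52,10.1,0.45,30,34,29,22,21,21
Bunch_09,76,9.5,0.40,41,43,48,20,20,19
Bunch_10,40,9.5,0.38,29,24,24,22,21,20
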