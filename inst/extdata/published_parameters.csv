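preset,parameter,value
human_wt_saturation,bmax,598111
human_wt_saturation,pKd_radioligand,9.76
mouse_wt_saturation,bmax,21027
mouse_wt_saturation,pKd_radioligand,9.76
human_wt_LY298,pKd_radioligand,9.76
human_wt_LY298,pKb,5.65
human_wt_LY298,log_alpha_prime,0
human_wt_LY298,pKi.ACh,4.50
human_wt_LY298,log_alpha.ACh,2.59
human_wt_LY298,pKi.Ipx,8.30
human_wt_LY298,log_alpha.Ipx,1.86
human_wt_VU154,pKd_radioligand,9.76
human_wt_VU154,pKb,5.83
human_wt_VU154,log_alpha_prime,0
human_wt_VU154,pKi.ACh,4.40
human_wt_VU154,log_alpha.ACh,1.61
human_wt_VU154,pKi.Ipx,8.19
human_wt_VU154,log_alpha.Ipx,1.03
mouse_wt_LY298,pKd_radioligand,9.76
mouse_wt_LY298,pKb,5.74
mouse_wt_LY298,log_alpha_prime,0
mouse_wt_LY298,pKi.ACh,4.52
mouse_wt_LY298,log_alpha.ACh,1.78
mouse_wt_LY298,pKi.Ipx,8.55
mouse_wt_LY298,log_alpha.Ipx,1.30
mouse_wt_VU154,pKd_radioligand,9.76
mouse_wt_VU154,pKb,6.07
mouse_wt_VU154,log_alpha_prime,0
mouse_wt_VU154,pKi.ACh,4.59
mouse_wt_VU154,log_alpha.ACh,2.43
mouse_wt_VU154,pKi.Ipx,8.57
mouse_wt_VU154,log_alpha.Ipx,1.75
q184a_LY298,pKd_radioligand,9.99
q184a_LY298,pKb,6.23
q184a_LY298,log_alpha_prime,-1.10
q184a_LY298,pKi.ACh,5.24
q184a_LY298,log_alpha.ACh,1.28
q184a_LY298,pKi.Ipx,8.74
q184a_LY298,log_alpha.Ipx,1.27
perk_wt_ACh_LY298,pKb,4.89
perk_wt_ACh_LY298,log_tau_B,1.10
perk_wt_ACh_LY298,pKa.ACh,4.51
perk_wt_ACh_LY298,log_tau_A.ACh,2.96
perk_wt_ACh_LY298,log_alphabeta.ACh,2.43
perk_wt_ACh_LY298,log_alpha.ACh,1.97
trupath_wt_LY298,pKb,5.65
trupath_wt_LY298,log_tau_B,1.02
trupath_wt_LY298,pKa.ACh,4.50
trupath_wt_LY298,log_tau_A.ACh,2.71
trupath_wt_LY298,log_alphabeta.ACh,2.01
trupath_wt_LY298,log_alpha.ACh,2.59
trupath_wt_LY298,pKa.Ipx,8.30
trupath_wt_LY298,log_tau_A.Ipx,1.49
trupath_wt_LY298,log_alphabeta.Ipx,1.96
trupath_wt_LY298,log_alpha.Ipx,1.86
trupath_wt_VU154,pKb,5.83
trupath_wt_VU154,log_tau_B,-0.55
trupath_wt_VU154,pKa.ACh,4.40
trupath_wt_VU154,log_tau_A.ACh,2.71
trupath_wt_VU154,log_alphabeta.ACh,1.22
trupath_wt_VU154,log_alpha.ACh,1.61
trupath_wt_VU154,pKa.Ipx,8.19
trupath_wt_VU154,log_tau_A.Ipx,1.49
trupath_wt_VU154,log_alphabeta.Ipx,0.20
trupath_wt_VU154,log_alpha.Ipx,1.03
perk_wt_LY298,pKb,5.65
perk_wt_LY298,log_tau_B,1.19
perk_wt_LY298,pKa.ACh,4.50
perk_wt_LY298,log_tau_A.ACh,3.27
perk_wt_LY298,log_alphabeta.ACh,2.29
perk_wt_LY298,log_alpha.ACh,2.59
perk_wt_LY298,pKa.Ipx,8.30
perk_wt_LY298,log_tau_A.Ipx,1.74
perk_wt_LY298,log_alphabeta.Ipx,1.08
perk_wt_LY298,log_alpha.Ipx,1.86
perk_wt_VU154,pKb,5.83
perk_wt_VU154,log_tau_B,0.11
perk_wt_VU154,pKa.ACh,4.40
perk_wt_VU154,log_tau_A.ACh,3.27
perk_wt_VU154,log_alphabeta.ACh,0.88
perk_wt_VU154,log_alpha.ACh,1.61
perk_wt_VU154,pKa.Ipx,8.19
perk_wt_VU154,log_tau_A.Ipx,1.74
perk_wt_VU154,log_alphabeta.Ipx,0.66
perk_wt_VU154,log_alpha.Ipx,1.03
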