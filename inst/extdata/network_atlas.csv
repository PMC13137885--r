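roi_id,network,hemisphere,x,y,z
dmn_l_dmpfc,dmn,L,-27,23,48
dmn_r_dmpfc,dmn,R,27,23,48
dmn_r_ppc,dmn,R,41,-60,29
dmn_l_sts,dmn,L,-64,-20,-9
dmn_r_sts,dmn,R,64,-20,-9
dmn_l_vmpfc,dmn,L,-7,49,18
dmn_r_vmpfc,dmn,R,7,49,18
dmn_l_hf,dmn,L,-25,-32,-18
dmn_r_hf,dmn,R,25,-32,-18
dmn_l_pcc,dmn,L,-7,-52,26
dmn_r_pcc,dmn,R,7,-52,26
lang_l_temppole,language,L,-52,6,-18
lang_l_antmtg,language,L,-54,-14,-14
lang_l_ifg_tri,language,L,-48,28,-4
lang_l_postmtg,language,L,-56,-38,0
lang_l_ag,language,L,-52,-54,12
lang_l_ifg_op,language,L,-52,24,14
lang_l_latocc,language,L,-42,-68,24
lang_l_precg,language,L,-44,-80,50
md_l_ppc,md,L,-18,-66,52
md_r_ppc,md,R,18,-66,52
md_l_midpar,md,L,-44,-56,52
md_r_midpar,md,R,44,-56,52
md_l_antpar,md,L,-48,-38,48
md_r_antpar,md,R,48,-38,48
md_l_sfg,md,L,-30,0,58
md_r_sfg,md,R,30,0,58
md_l_precg_a,md,L,-48,6,38
md_r_precg_a,md,R,48,6,38
md_l_precg_b,md,L,-50,12,22
md_r_precg_b,md,R,50,12,22
md_l_mfg,md,L,-42,30,30
md_r_mfg,md,R,42,30,30
md_l_orbmfg,md,L,-34,54,12
md_r_orbmfg,md,R,34,54,12
md_l_insula,md,L,-34,22,-2
md_r_insula,md,R,34,22,-2
md_l_medfg,md,L,-8,20,42
md_r_medfg,md,R,8,20,42
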