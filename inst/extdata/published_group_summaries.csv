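comparison,group1,m1,sem1,n1,group2,m2,sem2,n2,t_printed,tol_abs
pct_vz_24h_cag_vs_wnt_reporter,CAG-BFP,47.97,1.23,4,TOP-GFP,43.41,2.45,4,1.67,0.02
pct_vz_24h_cag_vs_hes5_reporter,CAG-BFP,50.51,0.66,4,Hes5-dsRed,81.69,5.47,4,5.66,0.02
pct_vz_24h_cag_vs_cbfre_reporter,pCAG-BFP,49.67,0.69,4,CBFRE-GFP,83.55,1.91,4,16.71,0.03
pct_vz_24h_cag_vs_emx2,CAG-BFP,50.51,0.66,4,Emx2-GFP,80.13,4.75,4,6.17,0.02
pct_astrocytes_cag_vs_hes5_lineage,CAG-CreERT2,18.57,3.28,4,Hes5-CreERT2,15.72,2.78,4,0.66,0.02
pct_cp_dual_cag_vs_hes5,CAG+,25.28,1.84,4,Hes5+,0.90,0.36,4,12.95,0.06
pct_vz_dual_cag_vs_hes5,CAG+,32.21,2.42,4,Hes5+,59.25,2.18,4,8.28,0.03
pct_svz_dual_cag_vs_hes5,CAG+,17.44,1.46,4,Hes5+,22.40,0.84,4,2.93,0.02
pct_cux1_lineage_cag_vs_hes5,CAG-CreERT2,38.70,1.98,3,Hes5-CreERT2,83.96,7.30,3,5.98,0.02
pct_satb2_lineage_cag_vs_hes5,CAG-CreERT2,56.96,2.34,3,Hes5-CreERT2,90.81,0.89,3,13.51,0.02
pct_pax6_ctrl_vs_sox9oe,PCIG,18.02,1.89,4,PCIG-FL-Sox9,53.42,5.90,4,5.72,0.02
pct_dcx_ctrl_vs_sox9oe,PCIG,68.07,2.17,4,PCIG-FL-Sox9,38.85,2.77,4,8.31,0.02
mfi_sox9_scshrna_vs_s9shrna,sc-shRNA,88.33,5.46,3,S9-shRNA,40.72,6.20,3,5.76,0.02
pct_cp_scshrna_vs_s9shrna,sc-shRNA,19.62,6.10,4,S9-shRNA,37.75,2.75,4,2.71,0.02
pct_pvim_ctrl_vs_sox9oe,PCIG,11.02,0.67,4,PCIG-FL-Sox9,2.40,0.47,4,10.52,0.02
pct_edu_ctrl_vs_sox9oe,PCIG,37.95,2.70,4,PCIG-FL-Sox9,10.52,3.01,4,6.79,0.02
pct_ki67_ctrl_vs_sox9oe,PCIG,96.03,1.06,4,PCIG-FL-Sox9,48.61,5.29,4,8.79,0.02
pct_ivz_ctrl_vs_sox9oe,PCIG,43.27,4.75,4,PCIG-FL-Sox9,65.37,1.63,4,4.40,0.02
pct_mcm2_ctrl_vs_sox9oe,PCIG,97.65,0.63,4,PCIG-FL-Sox9,90.25,1.20,4,5.47,0.02
pct_mcm2pos_ki67neg_ctrl_vs_sox9oe,PCIG,4.73,0.79,4,PCIG-FL-Sox9,38.30,1.49,4,19.93,0.03
ts_hours_ctrl_vs_sox9oe,PCIG,5.31,0.39,4,PCIG-FL-Sox9,8.66,0.74,4,3.99,0.02
tc_mcm2_hours_ctrl_vs_sox9oe,PCIG,15.14,0.91,4,PCIG-FL-Sox9,49.21,3.91,4,8.49,0.02
tc_ki67_hours_ctrl_vs_sox9oe,PCIG,14.41,0.86,4,PCIG-FL-Sox9,28.35,2.25,4,5.80,0.02
pct_flashtag_ul_ctrl_vs_sox9oe,PCIG,4.09,0.47,3,PCIG-FL-Sox9,36.36,4.17,3,7.69,0.02
pct_cux1_p12_ctrl_vs_sox9oe,PCIG,26.14,3.14,4,PCIG-FL-Sox9,44.10,4.48,4,3.28,0.02
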