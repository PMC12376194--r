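analyte_cas,assay_endpoint_id,acc_um,exclusion_reason
124-48-1,SYN_ATG_TRANS_up,0.05,none
124-48-1,SYN_NVS_NR_bind,0.8,none
124-48-1,SYN_TOX21_lum,1.5,baseline
75-27-4,SYN_ATG_TRANS_up,0.9,none
75-27-4,SYN_ACEA_prolif,5.0,none
75-27-4,SYN_OT_cytotox,2.2,unreliable_curve
67-66-3,SYN_ATG_TRANS_up,8.0,none
67-66-3,SYN_ACEA_prolif,20.0,none
75-25-2,SYN_ATG_TRANS_up,1.2,none
75-25-2,SYN_ACEA_prolif,6.0,none
1912-24-9,SYN_NVS_ADME,0.6,none
1912-24-9,SYN_ATG_TRANS_up,3.0,none
1912-24-9,SYN_BSK_cyto,0.4,nonspecific_endpoint
122-34-9,SYN_NVS_ADME,1.5,none
51218-45-2,SYN_NVS_ADME,2.0,none
80474-14-2,SYN_NVS_NR_hGR,0.001,none
80474-14-2,SYN_ATG_GRE_cis,0.004,none
298-46-4,SYN_ATG_TRANS_up,10,none
335-67-1,SYN_NVS_NR_hPPARg,30,none
1763-23-1,SYN_NVS_NR_hPPARg,25,none
375-22-4,SYN_NVS_NR_hPPARg,100,none
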