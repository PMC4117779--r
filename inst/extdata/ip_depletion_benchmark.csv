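experiment_id,cell_line,replicate,n_htr_per_cell,r_act,r_htr,htr_per_ul_elution,htert_per_ul_elution,reported_rnp_per_cell,reported_htert_per_cell
ip1,HEK293T,1,800,0.65,0.94,9.2e6,15e6,146,237
ip2,HEK293T,2,800,0.48,0.84,8.2e6,11e6,245,322
ip3,HEK293T,3,800,0.44,0.77,NA,NA,332,NA
ip4,HeLa,1,1300,0.56,0.91,1.2e6,1.7e6,255,382
ip5,HeLa,2,1300,0.37,0.88,1.3e6,3.1e6,255,608
ip6,HeLa,3,1300,0.33,0.88,1.4e6,3.3e6,222,534
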