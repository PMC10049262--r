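comparison,mz,numerator_group,denominator_group,mean_numerator,mean_denominator,log2fc_printed
BRAF_MUT_vs_WT,768.3,BRAF_MUT,WT,3.52,2.31,0.61
BRAF_MUT_vs_WT,1026.5,BRAF_MUT,WT,5.63,3.18,0.82
BRAF_MUT_vs_WT,1252.6,BRAF_MUT,WT,3.91,2.88,0.44
BRAF_MUT_vs_WT,1300.6,BRAF_MUT,WT,4.16,2.65,0.65
BRAF_MUT_vs_WT,1336.6,BRAF_MUT,WT,2.64,2.09,0.33
NRAS_WT_vs_MUT,715.3,WT,NRAS_MUT,15.47,7.38,1.067
NRAS_WT_vs_MUT,733.3,WT,NRAS_MUT,9.57,2.99,1.67
NRAS_WT_vs_MUT,807.3,WT,NRAS_MUT,13.25,5.32,1.31
NRAS_WT_vs_MUT,826.4,WT,NRAS_MUT,6.8,2.55,1.4
NRAS_WT_vs_MUT,837.4,WT,NRAS_MUT,25.22,35.48,-0.49
NRAS_WT_vs_MUT,910.4,WT,NRAS_MUT,24.18,4.39,2.45
NRAS_WT_vs_MUT,982.4,WT,NRAS_MUT,24.29,6.64,1.87
NRAS_WT_vs_MUT,1082.5,WT,NRAS_MUT,14.93,4.97,1.58
NRAS_WT_vs_MUT,1091.5,WT,NRAS_MUT,12.2,3.78,1.69
NRAS_WT_vs_MUT,1129.5,WT,NRAS_MUT,7.74,6.55,0.24
NRAS_WT_vs_MUT,1222.6,WT,NRAS_MUT,9.3,5.44,0.77
NRAS_WT_vs_MUT,1259.6,WT,NRAS_MUT,5.44,4.12,0.39
NRAS_WT_vs_MUT,1262.6,WT,NRAS_MUT,7.46,5.81,0.36
NRAS_WT_vs_MUT,1512.7,WT,NRAS_MUT,13.16,5.15,1.35
NRAS_WT_vs_MUT,1678.8,WT,NRAS_MUT,4.35,3.94,0.14
NRAS_WT_vs_MUT,1783.8,WT,NRAS_MUT,5.86,3.63,0.69
BRAF_MUT_vs_NRAS_MUT,944.4,BRAF_MUT,NRAS_MUT,52.37,37.35,0.48
BRAF_MUT_vs_NRAS_MUT,1825.9,BRAF_MUT,NRAS_MUT,4.67,6.45,-0.46
BRAF_MUT_vs_NRAS_MUT,2169,BRAF_MUT,NRAS_MUT,2.91,3.7,-0.34
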