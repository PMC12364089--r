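band,state,pct_2017,n_2017,pct_2027,n_2027
50-64,Fit,38.36,7689306,34.85,7580985
65-74,Fit,14.04,2813696,11.92,2593440
75-84,Fit,4.99,1000342,4.15,902502
85+,Fit,1.09,218329,0.42,92415
50-64,Mild,9.43,1890524,11.31,2460389
65-74,Mild,9.34,1871634,10.35,2252318
75-84,Mild,5.87,1175918,5.95,1294121
85+,Mild,2.38,476438,1.39,302014
50-64,Moderate,1.93,387793,3.02,657204
65-74,Moderate,2.60,521885,2.40,521665
75-84,Moderate,3.42,686230,4.02,875014
85+,Moderate,2.3,460649,1.77,384709
50-64,Severe,0.32,63186,0.64,139944
65-74,Severe,0.74,148237,0.96,208367
75-84,Severe,1.61,323287,3.61,785707
85+,Severe,1.59,318311,3.24,704303
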