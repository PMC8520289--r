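"study_id","comparison_id","treat_successes","treat_failures","treat_total","ctrl_successes","ctrl_failures","ctrl_total","margin_pct","analysis_population","year","reported_ci_method","randomization_label"
"S1","S1_C1",80,,100,78,,100,10,"ITT",2012,"wald","1:1"
"S2","S2_C1",60,,60,58,,60,10,"ITT",2015,,"1:1"
"S3","S3_C1",,5,120,,8,118,12.5,"PP",2008,"miettinen_nurminen","1:1"
"S4","S4_C1",150,,182,148,,180,,"unspecified",2019,,"1:1"
"S5","S5_C1",190,,200,90,,100,10,"ITT",2010,"newcombe","2:1"
"S5","S5_C2",95,,100,90,,100,10,"ITT",2010,"newcombe","1:1"
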