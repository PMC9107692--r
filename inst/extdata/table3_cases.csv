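case,ihc_subtype_printed,molecular_subtype,basal_marker,ki67_pct,pr_pct,er_pct,grade,p53_pos,immune_group,tils_level,ror_class,recurrence,ck56_pos,egfr_pos,ck14_pos,ambiguous_parse
1,LumB,Basal,positive,80,0,1,3,TRUE,istrong,high,high,yes_metastasis,TRUE,TRUE,TRUE,FALSE
2,LumB,Basal,positive,60,30,2,3,TRUE,istrong,high,medium,no,TRUE,TRUE,FALSE,FALSE
3,LumB,Basal,positive,60,0,1,2,TRUE,iweak,low,medium,no,FALSE,TRUE,FALSE,FALSE
4,LumB,Basal,positive,60,5,0,2,FALSE,istrong,high,high,yes_metastasis,TRUE,TRUE,TRUE,TRUE
5,LumB,Basal,positive,90,0,10,3,TRUE,iweak,low,high,no,FALSE,TRUE,FALSE,FALSE
6,LumB,Basal,positive,40,10,5,3,TRUE,istrong,high,high,yes_metastasis,TRUE,TRUE,FALSE,FALSE
7,LumB,LumA,positive,30,90,90,2,FALSE,iweak,low,medium,no,FALSE,TRUE,FALSE,FALSE
8,LumA,LumA,positive,6,60,80,2,FALSE,iweak,low,low,yes_metastasis,FALSE,TRUE,FALSE,TRUE
9,LumB,LumA,positive,10,0,95,1,FALSE,iweak,low,medium,no,FALSE,TRUE,FALSE,TRUE
10,LumB,LumB,positive,20,95,95,2,FALSE,iweak,low,medium,no,FALSE,TRUE,FALSE,FALSE
11,LumA,LumA,positive,3,100,100,1,TRUE,iweak,low,low,no,FALSE,TRUE,FALSE,FALSE
12,LumA,LumA,positive,10,30,60,1,FALSE,iweak,low,low,yes_metastasis,FALSE,TRUE,FALSE,FALSE
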