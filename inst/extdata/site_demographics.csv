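group,site,characteristic,statistic,n,value,value2
case,SH,n,count,3028,3028,
case,GSH,n,count,491,491,
case,KYUH,n,count,539,539,
case,AJUH,n,count,1003,1003,
case,SNUH,n,count,2616,2616,
case,NCC,n,count,966,966,
control,SH,n,count,11018,11018,
control,GSH,n,count,1689,1689,
control,KYUH,n,count,1954,1954,
control,AJUH,n,count,3328,3328,
control,SNUH,n,count,9558,9558,
control,NCC,n,count,3465,3465,
case,SH,age,mean_sd,3028,61.83,15.23
case,GSH,age,mean_sd,491,62.6,15.04
case,KYUH,age,mean_sd,539,67.91,13.64
case,AJUH,age,mean_sd,1003,59.52,15.79
case,SNUH,age,mean_sd,2616,57.89,16.49
case,NCC,age,mean_sd,966,60.55,12.24
control,SH,age,mean_sd,11018,61.14,15.37
control,GSH,age,mean_sd,1689,62.26,14.81
control,KYUH,age,mean_sd,1954,67.71,13.55
control,AJUH,age,mean_sd,3328,59.67,15.77
control,SNUH,age,mean_sd,9558,57.46,16.61
control,NCC,age,mean_sd,3465,60.14,12.71
case,SH,male,count_pct,3028,1965,64.89
case,GSH,male,count_pct,491,286,58.25
case,KYUH,male,count_pct,539,360,66.79
case,AJUH,male,count_pct,1003,628,62.61
case,SNUH,male,count_pct,2616,1652,63.15
case,NCC,male,count_pct,966,569,58.9
control,SH,male,count_pct,11018,7092,64.37
control,GSH,male,count_pct,1689,985,58.32
control,KYUH,male,count_pct,1954,950,48.62
control,AJUH,male,count_pct,3328,1765,53.03
control,SNUH,male,count_pct,9558,4602,48.15
control,NCC,male,count_pct,3465,2018,58.24
case,SH,sepsis,count_pct,3028,325,10.73
case,GSH,sepsis,count_pct,491,50,10.18
case,KYUH,sepsis,count_pct,539,7,1.3
case,AJUH,sepsis,count_pct,1003,139,13.86
case,SNUH,sepsis,count_pct,2616,40,1.53
case,NCC,sepsis,count_pct,966,1,0.1
control,SH,sepsis,count_pct,11018,373,3.39
control,GSH,sepsis,count_pct,1689,37,2.19
control,KYUH,sepsis,count_pct,1954,21,1.07
control,AJUH,sepsis,count_pct,3328,128,3.85
control,SNUH,sepsis,count_pct,9558,41,0.43
control,NCC,sepsis,count_pct,3465,1,0.03
case,SH,scr,mean_sd,3028,0.46,0.74
case,GSH,scr,mean_sd,491,0.79,0.23
case,KYUH,scr,mean_sd,539,0.99,0.37
case,AJUH,scr,mean_sd,1003,0.87,0.37
case,SNUH,scr,mean_sd,2616,0.87,0.47
case,NCC,scr,mean_sd,966,1.01,0.29
control,SH,scr,mean_sd,11018,0.44,0.51
control,GSH,scr,mean_sd,1689,0.76,0.19
control,KYUH,scr,mean_sd,1954,0.98,0.22
control,AJUH,scr,mean_sd,3328,0.84,0.2
control,SNUH,scr,mean_sd,9558,0.83,0.18
control,NCC,scr,mean_sd,3465,0.98,0.16
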