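variable,pre_style,pre_center,pre_sd,pre_q1,pre_q3,post_style,post_center,post_sd,post_q1,post_q3,mean_diff,ci_low,ci_high,p_text
LAI,mean_sd,1.21,0.10,NA,NA,mean_sd,1.26,0.08,NA,NA,-0.06,-0.09,-0.02,.002
LVEDVi,mean_sd,4.21,0.80,NA,NA,mean_sd,3.69,0.86,NA,NA,0.52,0.22,0.81,.002
LVESVi,mean_sd,1.52,0.35,NA,NA,mean_sd,1.24,0.38,NA,NA,0.28,0.12,0.44,.002
LVEF_pct,mean_sd,64.01,5.24,NA,NA,mean_sd,66.44,6.92,NA,NA,-2.43,-5.82,0.96,.1
LVSVi,mean_sd,2.7,0.58,NA,NA,mean_sd,2.45,0.61,NA,NA,0.24,0.01,0.48,.04
RVoli,mean_sd,1.04,0.52,NA,NA,mean_sd,0.73,0.50,NA,NA,0.31,0.12,0.5,.003
RF_pct,mean_sd,37.1,11.04,NA,NA,mean_sd,27.35,12.22,NA,NA,9.75,5.16,14.34,<.001
LAESVi,mean_sd,1.94,0.69,NA,NA,median_iqr,1.51,NA,1.125,1.833,0.37,0.17,0.57,<.001
LAEDVi,mean_sd,0.96,0.30,NA,NA,mean_sd,0.78,0.24,NA,NA,0.18,0.08,0.28,.001
Ea,mean_sd,64.55,18.94,NA,NA,mean_sd,60.81,20.01,NA,NA,3.74,-4.7,12.18,.4
ADI_x1000,median_iqr,5.379,NA,4.456,6.616,mean_sd,5.15,1.48,NA,NA,NA,NA,NA,.6
MBP,mean_sd,89.50,22.76,NA,NA,mean_sd,93.25,11.82,NA,NA,-3.75,-15.27,7.77,.5
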