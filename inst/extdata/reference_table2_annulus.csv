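metric,phase,pre_mean,pre_sd,post_mean,post_sd,mean_diff,ci_low,ci_high,p_text
MAA,MD,10.28,1.39,10.09,1.61,0.19,-0.26,0.64,.4
MAA,LD,10.45,1.47,10.23,1.78,0.22,-0.28,0.72,.4
MAA,ED,8.72,1.43,8.39,1.26,0.33,-0.02,0.69,.06
MAA,MS,9.69,1.81,9.32,1.97,0.37,-0.15,0.88,.2
MAA,ES,9.56,2.08,8.19,1.67,1.38,0.79,1.97,<.001
APD,MD,10.68,0.93,10.59,1.23,0.09,-0.29,0.46,.6
APD,LD,10.85,0.99,10.69,1.30,0.17,-0.24,0.57,.4
APD,ED,9.75,0.93,9.54,0.99,0.21,-0.12,0.55,.2
APD,MS,10.52,1.39,10.56,1.43,-0.04,-0.45,0.38,.9
APD,ES,10.96,1.49,9.93,1.30,1.03,0.54,1.53,<.001
ICD,MD,12.10,0.94,11.87,0.94,0.23,-0.15,0.6,.2
ICD,LD,12.17,0.87,12.00,1.10,0.16,-0.17,0.49,.3
ICD,ED,11.18,0.97,10.86,0.99,0.31,-0.03,0.65,.07
ICD,MS,11.57,0.96,11.29,1.08,0.28,0.01,0.56,.04
ICD,ES,11.32,1.19,10.57,0.99,0.75,0.44,1.06,<.001
TTD,MD,6.21,0.58,6.40,0.61,-0.19,-0.41,0.03,.09
TTD,LD,6.36,0.53,6.35,0.65,0.01,-0.23,0.25,.9
TTD,ED,6.17,0.56,6.19,0.64,0.02,-0.20,0.17,.9
TTD,MS,6.28,0.61,6.09,0.67,0.19,-0.02,0.4,.07
TTD,ES,6.28,0.78,6.02,0.64,0.27,-0.002,0.5,.05
SI,MD,0.88,0.07,0.89,0.09,-0.01,-0.05,0.03,.6
SI,LD,0.89,0.07,0.89,0.09,0.002,-0.03,0.04,.9
SI,ED,0.87,0.06,0.88,0.08,-0.01,-0.04,0.03,.7
SI,MS,0.91,0.07,0.94,0.09,-0.03,-0.06,0.004,.08
SI,ES,0.97,0.08,0.94,0.09,0.03,-0.003,0.06,.08
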