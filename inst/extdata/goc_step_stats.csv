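ptt,dist_mean,dist_sd,dist_min,dist_max,dist_total,speed_mean,speed_sd,speed_min,speed_max,speed_transiting,speed_ars,speed_uncertain
824,27.89,22.8,0.66,115.4,6136.6,1.16,0.95,0.03,4.81,NA,1.01,0.25
830,23.51,14.68,2.57,64.68,1034.55,0.98,0.61,0.11,2.69,NA,0.96,1.58
833,27.34,22.06,0.66,115.4,6861.25,1.14,0.92,0.03,4.81,NA,0.96,0.21
834,26.33,21.76,0.66,115.4,7108.39,1.1,0.91,0.03,4.81,NA,0.5,1.18
836,23.38,21.36,0.07,129,9867.44,0.97,0.89,0,5.38,5.09,0.66,0.06
843,22.94,21.18,0.07,129,10252.9,0.96,0.88,0,5.38,NA,0.65,0.37
849,28.31,23.29,0.66,115.4,5718.87,1.18,0.97,0.03,4.81,2.54,1.1,0.55
23038,23.49,21.23,0.07,129,13199.65,0.98,0.88,0,5.38,2.5,0.88,0.03
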