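model,term,estimate,ci_low,ci_high
full_1,share_high,-12.112,-12.385,-11.839
full_1,share_med,-2.541,-2.887,-2.195
full_1,share_low,2.868,2.454,3.282
full_1,collab_low,-2.314,-2.409,-2.219
full_1,collab_high,-1.980,-2.095,-1.865
full_1,landing_risk_high,-0.005,-0.005,-0.004
full_1,landing_risk_low,-0.005,-0.006,-0.003
full_1,time_high_risk,0.033,0.032,0.034
full_1,time_low_risk,0.002,-0.000,0.005
full_2,share_high,-20.838,-21.095,-20.580
full_2,share_med,-12.473,-12.812,-12.134
full_2,share_low,-13.702,-14.113,-13.292
full_2,collab_low,-2.310,-2.405,-2.216
full_2,collab_high,-1.990,-2.105,-1.875
full_2,landing_risk_high,-0.005,-0.005,-0.004
full_2,landing_risk_low,-0.007,-0.009,-0.006
full_2,time_high_risk,0.032,0.031,0.033
full_2,time_low_risk,-0.001,-0.003,0.001
full_2,share_high_sq,45.598,45.525,45.671
full_2,share_med_sq,103.198,103.155,103.240
full_2,share_low_sq,162.365,162.325,162.404
low_experience,share_high,-11.427,-11.786,-11.068
low_experience,share_med,-0.275,-0.727,0.177
low_experience,share_low,4.842,4.312,5.372
low_experience,collab_low,-3.153,-3.279,-3.026
low_experience,collab_high,-2.377,-2.528,-2.226
low_experience,landing_risk_high,-0.005,-0.005,-0.005
low_experience,landing_risk_low,-0.005,-0.007,-0.003
low_experience,time_high_risk,0.035,0.033,0.036
low_experience,time_low_risk,0.002,-0.001,0.005
medium_experience,share_high,-12.760,-13.327,-12.192
medium_experience,share_med,-5.585,-6.303,-4.867
medium_experience,share_low,-0.665,-1.549,0.219
medium_experience,collab_low,-1.322,-1.512,-1.131
medium_experience,collab_high,-1.192,-1.429,-0.955
medium_experience,landing_risk_high,-0.004,-0.005,-0.003
medium_experience,landing_risk_low,-0.002,-0.005,0.001
medium_experience,time_high_risk,0.030,0.028,0.032
medium_experience,time_low_risk,0.004,-0.001,0.008
high_experience,share_high,-13.655,-14.298,-13.013
high_experience,share_med,-5.817,-6.642,-4.993
high_experience,share_low,-0.774,-1.800,0.251
high_experience,collab_low,-1.035,-1.248,-0.822
high_experience,collab_high,-1.503,-1.774,-1.232
high_experience,landing_risk_high,-0.004,-0.005,-0.003
high_experience,landing_risk_low,-0.005,-0.007,-0.002
high_experience,time_high_risk,0.030,0.027,0.032
high_experience,time_low_risk,0.004,-0.001,0.010
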