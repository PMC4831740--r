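model,label,p1,p2,p3,p1_name,p2_name,p3_name
saturation,I2KI,0.065,0.357,1.108,I0,Imax,k_per_day
saturation,PTA,0.068,0.648,0.489,I0,Imax,k_per_day
saturation,PMA,0.073,0.401,0.920,I0,Imax,k_per_day
staining_time,90,1.007,0.313,0.90,A_days,c_per_mm,level
staining_time,95,1.336,0.315,0.95,A_days,c_per_mm,level
staining_time,99,2.100,0.317,0.99,A_days,c_per_mm,level
front,PTA,3.094,0.367,,C_mm,K_per_day,
front,PMA,2.056,0.607,,C_mm,K_per_day,
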