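team_id,mean_demand,m_a,vmr_a,m_g,vmr_g,gini_s,m_s_implied
2,183.46,1.99,1.10,3.61,3.18,0.79,25.50
5,132.30,1.58,1.30,3.00,3.72,0.74,27.93
9,206.06,3.69,1.12,3.24,3.13,0.78,17.25
11,125.41,2.43,1.64,3.06,1.97,0.79,16.85
15,211.13,3.06,1.28,2.78,2.15,0.77,24.81
38,268.71,3.64,1.78,3.82,3.23,0.81,19.32
39,159.07,3.49,1.68,2.68,2.51,0.78,17.03
40,265.53,3.04,1.19,3.60,3.50,0.75,24.29
41,290.75,5.33,0.90,3.31,3.44,0.82,16.49
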