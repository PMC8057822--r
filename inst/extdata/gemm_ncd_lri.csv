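age_bracket,theta,theta_se,theta_lower,theta_upper,alpha,mu,nu
25-29,0.1585,0.01477,0.12955,0.18745,1.6,15.5,36.8
30-34,0.1577,0.0147,0.12889,0.18651,1.6,15.5,36.8
35-39,0.157,0.01463,0.12833,0.18567,1.6,15.5,36.8
40-44,0.1558,0.0145,0.12738,0.18422,1.6,15.5,36.8
45-49,0.1532,0.01425,0.12527,0.18113,1.6,15.5,36.8
50-54,0.1499,0.01394,0.12258,0.17722,1.6,15.5,36.8
55-59,0.1462,0.01361,0.11952,0.17288,1.6,15.5,36.8
60-64,0.1421,0.01325,0.11613,0.16807,1.6,15.5,36.8
65-69,0.1374,0.01284,0.11223,0.16257,1.6,15.5,36.8
70-74,0.1319,0.01234,0.10771,0.15609,1.6,15.5,36.8
75-79,0.1253,0.01174,0.10229,0.14831,1.6,15.5,36.8
80+,0.1141,0.01071,0.09311,0.13509,1.6,15.5,36.8
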