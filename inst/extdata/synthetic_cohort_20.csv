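patient_id,age,sex,npt_positive,spt_timothy,spt_bermuda,total_ige,sige_timothy,sige_bermuda,sige_phl_p_1,sige_phl_p_4,sige_phl_p_5,sige_phl_p_7,sige_phl_p_12,sige_cyn_d_1,vas_severity_retro,vas_drug_efficacy
P0001,13.5,F,1,12.6,7,112.5,3.91,6.85,31.64,26.91,31.64,0.1,0.1,0.1,8,7
P0002,17.2,M,1,7.9,7.7,2416.4,100,100,74.02,53.54,3.16,0.1,0.1,100,7,10
P0003,12.5,M,0,6.2,5.6,727.2,27.73,0.1,0.1,79.46,0.1,0.1,0.1,11.71,2,6
P0004,14.9,F,1,7.7,8.1,780.6,100,0.1,21.23,0.1,0.1,0.1,0.1,38.5,10,9
P0005,12.2,M,1,9.6,2.6,374.9,73.93,0.1,100,28.76,0.1,0.1,0.1,0.1,5,9
P0006,11.7,M,1,7.6,8.1,365.6,65.69,54.16,65.69,59.27,18.34,0.1,0.1,65.69,7,7
P0007,10.2,F,1,8,9,99,16.12,0.51,36.04,0.1,0.1,0.1,0.1,36.04,9,7
P0008,12.9,F,1,10.4,4.6,408.2,93.38,93.38,34.95,16.08,93.38,0.1,0.1,36.01,5,10
P0009,16.6,M,0,6.8,2.8,800.2,23.34,12.76,100,4.95,0.1,0.1,0.1,0.41,6,7
P0010,16.5,M,1,7.4,4.5,1223.6,100,100,86.7,55.02,0.1,0.36,0.1,100,4,4
P0011,11.6,M,0,11.3,6.7,1142.9,100,0.1,69.25,0.1,0.1,0.1,0.1,9.16,7,6
P0012,12.9,M,0,6.3,2.7,139.7,28.18,0.36,0.1,53.79,4.05,0.1,0.1,0.1,4,5
P0013,10.3,M,1,8.5,6.7,90.1,9.14,7.37,37.88,5.84,11.53,0.1,0.1,9.13,5,6
P0014,11.2,M,1,6.9,6.8,419.7,100,100,31.63,100,37.95,0.1,0.1,0.1,6,8
P0015,13.3,M,1,10.5,6.6,135.9,26.45,0.1,26.45,16.21,26.45,0.1,0.1,26.45,4,7
P0016,16.7,M,1,6.5,8.7,273,19.56,20.99,60.48,100,2.46,0.1,0.1,29.85,6,8
P0017,13.3,F,1,6.8,6.5,431.9,41.73,11.76,100,26.4,13.02,0.1,0.1,64.91,10,9
P0018,16.4,M,1,6.7,6.9,187.1,39.09,31.6,39.09,19.22,0.1,0.1,0.1,39.09,10,9
P0019,9.3,F,1,7.3,4.4,505.1,100,20.34,100,26.51,9.88,0.1,0.1,100,7,7
P0020,13.4,M,1,8.5,8.6,132.8,20.07,0.63,37.97,23.3,29.52,0.1,0.1,7.83,9,7
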