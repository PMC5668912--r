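# Synthetic-free transcription: folding of beta-hairpin chignolin at 300 K, 3 conditions x 22 checkpoints
# Aggregated native-state population (mean/SD/SE, percent, integer-rounded) and,
# where published, Kaplan-Meier / exponential folding-time estimates (ns, standard-mass
# time) for sets of 20 independent 500-million-step NTP MD folding simulations.
# Low-mass conditions (FF14SBlm, FF12MC) ran at dt = 1.00 fs and are credited on the
# numerically equivalent standard-mass axis (credit_fs = 3.16 = sqrt(10) x 1.00).
"condition","forcefield","temp_k","timestep_fs","credit_fs","steps_millions","agg_time_us","mean_pct","sd_pct","se_pct","tau_ns","lcl_ns","ucl_ns","events"
"FF12MC_dt1.00","FF12MC",300,1,3.16,10,0.632,3,7,2,NA,NA,NA,4
"FF12MC_dt1.00","FF12MC",300,1,3.16,20,1.264,7,17,4,NA,NA,NA,7
"FF12MC_dt1.00","FF12MC",300,1,3.16,30,1.896,14,22,5,87,53,145,15
"FF12MC_dt1.00","FF12MC",300,1,3.16,40,2.528,18,25,5,92,56,150,16
"FF12MC_dt1.00","FF12MC",300,1,3.16,50,3.16,22,26,6,82,53,129,19
"FF12MC_dt1.00","FF12MC",300,1,3.16,60,3.792,26,26,6,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,70,4.424,30,26,6,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,80,5.056,31,25,6,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,90,5.688,33,24,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,100,6.32,33,23,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,110,6.952,34,22,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,120,7.584,35,21,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,130,8.216,35,21,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,140,8.848,35,20,5,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,150,9.48,36,20,4,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,200,12.64,36,14,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,250,15.8,38,13,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,300,18.96,36,12,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,350,22.12,35,13,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,400,25.28,35,12,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,450,28.44,35,12,3,79,51,123,20
"FF12MC_dt1.00","FF12MC",300,1,3.16,500,31.6,35,12,3,79,51,123,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,10,0.632,3,8,2,NA,NA,NA,4
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,20,1.264,8,17,4,NA,NA,NA,10
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,30,1.896,16,23,5,95,55,163,13
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,40,2.528,21,22,5,74,47,118,18
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,50,3.16,24,21,5,73,47,114,19
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,60,3.792,28,21,5,74,48,117,19
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,70,4.424,31,20,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,80,5.056,34,20,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,90,5.688,36,20,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,100,6.32,38,19,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,110,6.952,38,18,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,120,7.584,37,17,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,130,8.216,37,17,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,140,8.848,37,17,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,150,9.48,37,17,4,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,200,12.64,39,15,3,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,250,15.8,39,15,3,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,300,18.96,38,13,3,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,350,22.12,37,12,3,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,400,25.28,37,11,2,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,450,28.44,37,9,2,72,47,112,20
"FF12MCstdm_dt3.16","FF12MCstdm",300,3.16,3.16,500,31.6,37,7,2,72,47,112,20
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,10,0.4,1,3,1,NA,NA,NA,2
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,20,0.8,2,6,1,NA,NA,NA,4
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,30,1.2,5,10,2,NA,NA,NA,9
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,40,1.6,8,12,3,NA,NA,NA,10
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,50,2,13,16,4,128,71,231,11
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,60,2.4,16,19,4,122,71,209,13
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,70,2.8,17,20,4,132,76,227,13
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,80,3.2,18,20,4,132,78,222,14
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,90,3.6,19,19,4,114,71,184,17
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,100,4,20,18,4,105,67,164,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,110,4.4,22,17,4,106,67,165,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,120,4.8,24,16,4,107,68,167,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,130,5.2,26,16,4,108,69,169,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,140,5.6,27,17,4,109,69,171,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,150,6,28,17,4,110,70,172,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,200,8,31,17,4,114,73,179,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,250,10,34,17,4,120,77,188,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,300,12,34,15,3,125,80,196,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,350,14,34,14,3,130,83,204,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,400,16,35,15,3,136,87,212,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,450,18,35,14,3,141,90,221,19
"FF12MCstdm_dt2.00","FF12MCstdm",300,2,2,500,20,35,13,3,147,94,230,19
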