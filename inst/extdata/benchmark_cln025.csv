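# Synthetic-free transcription: folding of beta-hairpin CLN025, 4 conditions x 10 checkpoints
# Aggregated native-state population (mean/SD/SE, percent, integer-rounded) and,
# where published, Kaplan-Meier / exponential folding-time estimates (ns, standard-mass
# time) for sets of 20 independent 500-million-step NTP MD folding simulations.
# Low-mass conditions (FF14SBlm, FF12MC) ran at dt = 1.00 fs and are credited on the
# numerically equivalent standard-mass axis (credit_fs = 3.16 = sqrt(10) x 1.00).
"condition","forcefield","temp_k","timestep_fs","credit_fs","steps_millions","agg_time_us","mean_pct","sd_pct","se_pct"
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,50,3.16,0,1,0
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,100,6.32,0,1,0
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,150,9.48,4,10,2
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,200,12.64,6,15,3
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,250,15.8,9,19,4
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,300,18.96,12,22,5
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,350,22.12,14,24,5
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,400,25.28,15,26,6
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,450,28.44,16,27,6
"FF14SBlm_dt1.00","FF14SBlm",277,1,3.16,500,31.6,17,28,6
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,50,3.16,0,0,0
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,100,6.32,4,11,3
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,150,9.48,6,17,4
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,200,12.64,9,21,5
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,250,15.8,12,24,5
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,300,18.96,15,24,5
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,350,22.12,18,25,6
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,400,25.28,21,26,6
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,450,28.44,23,28,6
"FF14SB_dt3.16","FF14SB",277,3.16,3.16,500,31.6,26,29,6
"FF14SB_dt2.00","FF14SB",277,2,2,50,2,0,0,0
"FF14SB_dt2.00","FF14SB",277,2,2,100,4,0,0,0
"FF14SB_dt2.00","FF14SB",277,2,2,150,6,0,1,0
"FF14SB_dt2.00","FF14SB",277,2,2,200,8,1,4,1
"FF14SB_dt2.00","FF14SB",277,2,2,250,10,3,8,2
"FF14SB_dt2.00","FF14SB",277,2,2,300,12,4,11,3
"FF14SB_dt2.00","FF14SB",277,2,2,350,14,5,14,3
"FF14SB_dt2.00","FF14SB",277,2,2,400,16,6,15,3
"FF14SB_dt2.00","FF14SB",277,2,2,450,18,8,17,4
"FF14SB_dt2.00","FF14SB",277,2,2,500,20,9,19,4
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,50,3.16,29,26,6
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,100,6.32,36,16,4
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,150,9.48,41,14,3
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,200,12.64,41,13,3
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,250,15.8,42,12,3
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,300,18.96,42,10,2
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,350,22.12,41,9,2
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,400,25.28,41,9,2
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,450,28.44,42,9,2
"FF12MCstdm_dt3.16","FF12MCstdm",340,3.16,3.16,500,31.6,41,9,2
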