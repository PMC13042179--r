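# Default parameters of the four planted sepsis physio-phenotype archetypes.
# Cohort-level targets (hr_mean, sdnn/rmssd/pnn50/lfhf, rr skewness, PPG AC
# skewness, AUC fractions, mortality, prevalences) are per-phenotype medians /
# rates of the reference sepsis cohort characteristics table; quantities that
# table does not print (waveform morphology details, day-2/7/28 support
# probabilities, covariate prevalences, respiratory rates) are fixed here once
# at clinically plausible values consistent with the directional statements of
# the source analysis (highest support burden in SP3, lowest in SP2,
# ventilation second-highest in SP1).
# hr_mean: ECG_HR_bpm median per phenotype (87.925 / 86.066 / 78.513 / 91.517)
# sdnn_target: HRV_SDNN median, ms (9.280 / 184.614 / 271.662 / 219.034)
# rmssd_target: HRV_RMSSD median, ms (8.879 / 249.684 / 373.849 / 320.049)
# pnn50_target: HRV_pNN50 median, percent (0 -> 0.3 floor / 9.028 / 25.362 / 71.455)
# lfhf_target: HRV_LFHF median (0.790 / 0.781 / 0.781 / 0.590)
# rr_skew_target: RR skewness median (0.107 / 5.965 / 3.293 / 2.364)
# rr_irregularity: level mapped from RR entropy medians (1.928 / 0.332 / 0.590 / 1.206)
# ppg_ac_skew_target: PPG_A_AC_skewness median (-0.384 / -1.345 / -0.167 / -0.386)
# ppg_rise_frac: relative systolic-rise fraction, from AUCos_nu ordering
# ppg_notch_prom: dicrotic notch prominence fraction (chosen)
# ppg_pat_ms: pulse-arrival delay, ms (chosen)
# resp_rate: breaths/min (chosen; sepsis-typical tachypnoea)
# mortality_28d: per-phenotype mortality rate (0.2429 / 0.1902 / 0.2877 / 0.2652)
# shock/vp/mv_d*: first-activation-style cumulative probabilities by day (chosen)
# p_sbp_low / p_rr_high / p_gcs_low: qSOFA-style covariate prevalences (chosen)
id,hr_mean,sdnn_target,rmssd_target,pnn50_target,lfhf_target,rr_skew_target,rr_irregularity,ppg_ac_skew_target,ppg_rise_frac,ppg_notch_prom,ppg_pat_ms,resp_rate,mortality_28d,shock_d2,shock_d7,shock_d28,vp_d2,vp_d7,vp_d28,mv_d2,mv_d7,mv_d28,p_sbp_low,p_rr_high,p_gcs_low
SP1,87.925,9.280,8.879,0.3,0.790,0.107,high,-0.384,0.30,0.25,220,21,0.2429,0.20,0.25,0.28,0.24,0.29,0.32,0.30,0.36,0.40,0.35,0.45,0.40
SP2,86.066,184.614,249.684,9.028,0.781,5.965,low,-1.345,0.27,0.30,200,18,0.1902,0.12,0.16,0.18,0.15,0.19,0.21,0.18,0.22,0.25,0.30,0.35,0.30
SP3,78.513,271.662,373.849,25.362,0.781,3.293,mid,-0.167,0.35,0.20,240,23,0.2877,0.30,0.38,0.42,0.34,0.41,0.45,0.35,0.42,0.46,0.50,0.55,0.45
SP4,91.517,219.034,320.049,71.455,0.590,2.364,mid,-0.386,0.36,0.25,230,20,0.2652,0.28,0.34,0.38,0.31,0.37,0.41,0.25,0.30,0.33,0.45,0.50,0.50
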