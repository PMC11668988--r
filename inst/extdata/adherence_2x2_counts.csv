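factor,level,reference,n,n_adherent,n_ref,n_ref_adherent,printed_or,printed_ci_low,printed_ci_high
sex,female,male,9553,1864,4007,1069,0.67,0.61,0.73
sex,other_or_not_specified,male,387,73,4007,1069,0.64,0.49,0.83
race_ethnicity,hispanic,nh_white,310,60,11109,2454,0.85,0.63,1.12
race_ethnicity,nh_asian_pi,nh_white,430,135,11109,2454,1.61,1.31,1.98
race_ethnicity,nh_black,nh_white,684,87,11109,2454,0.51,0.41,0.64
race_ethnicity,two_or_more,nh_white,293,61,11109,2454,0.93,0.69,1.23
race_ethnicity,other_or_not_specified,nh_white,1121,209,11109,2454,0.81,0.69,0.94
bmi_category,overweight,normal,2487,598,1994,727,0.55,0.48,0.63
bmi_category,obese,normal,1501,224,1994,727,0.31,0.26,0.36
bmi_category,severely_obese,normal,1375,88,1994,727,0.12,0.09,0.15
bmi_category,other_or_not_specified,normal,6590,1369,1994,727,0.46,0.41,0.51
age_group,30-39,18-29,2528,446,1511,389,0.62,0.53,0.72
age_group,40-49,18-29,2259,426,1511,389,0.67,0.57,0.78
age_group,50-59,18-29,2760,583,1511,389,0.77,0.67,0.90
age_group,60-69,18-29,3102,773,1511,389,0.96,0.83,1.10
age_group,70+,18-29,1787,389,1511,389,0.80,0.68,0.94
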