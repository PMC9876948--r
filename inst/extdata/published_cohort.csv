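quantity,value
n,132
histo_acute_inflamed,92
histo_gangrenous,4
histo_perforated,25
histo_negative,11
sex_male,79
sex_female,53
age_mean_years,24
age_sd_years,11.6
age_min_years,9
age_max_years,70
alvarado_score_mean,8.144
alvarado_score_sd,1.41
air_score_mean,7.69
air_score_sd,1.82
ripasa_score_mean,11.68
ripasa_score_sd,2.1
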