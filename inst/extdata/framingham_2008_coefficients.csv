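sex,term,beta,mean
male,ln_age,3.06117,NA
male,ln_tc,1.12370,NA
male,ln_hdl,-0.93263,NA
male,ln_sbp_untreated,1.93303,NA
male,ln_sbp_treated,1.99881,NA
male,smoker,0.65451,NA
male,diabetes,0.57367,NA
male,mean_lp,23.9802,NA
male,baseline_survival_10y,0.88936,NA
female,ln_age,2.32888,NA
female,ln_tc,1.20904,NA
female,ln_hdl,-0.70833,NA
female,ln_sbp_untreated,2.76157,NA
female,ln_sbp_treated,2.82263,NA
female,smoker,0.52873,NA
female,diabetes,0.69154,NA
female,mean_lp,26.1931,NA
female,baseline_survival_10y,0.95012,NA
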