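"stratum","variable","factor_1","factor_2","factor_3","factor_4"
"urban","age_ge60",0.05,0.87,0.1,-0.09
"urban","loss_labor_ability",-0.16,0.78,0.1,-0.25
"urban","illiterate",0.47,0.55,-0.25,0.18
"urban","living_alone",-0.12,-0.13,0.9,0.01
"urban","age_ge60_living_alone",-0.08,0.39,0.8,0.12
"urban","low_income",0.95,0,-0.08,0.1
"urban","low_income_seniors",0.76,-0.08,0.05,-0.28
"urban","low_income_households",0.93,0.06,-0.21,-0.07
"urban","households_one_room",-0.13,-0.28,0.2,0.78
"urban","households_le8m2",-0.03,0,-0.05,0.88
"rural","age_ge60",-0.23,0.12,0,0.8
"rural","loss_labor_ability",-0.18,-0.05,0.2,0.74
"rural","illiterate",0.79,0.12,-0.33,-0.09
"rural","living_alone",-0.04,-0.17,0.91,0.03
"rural","age_ge60_living_alone",0.4,0.15,0.7,0.34
"rural","low_income",-0.04,0.94,-0.11,0.08
"rural","low_income_seniors",-0.31,0.78,0.13,-0.34
"rural","low_income_households",0.22,0.68,-0.14,0.34
"rural","households_one_room",0.76,-0.22,0.34,-0.3
"rural","households_le8m2",0.76,-0.05,0.28,-0.22
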