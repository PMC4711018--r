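"stratum","row_var","col_var","printed","value","significance","note"
"urban","loss_labor_ability","age_ge60","0.540**",0.54,"**",""
"urban","illiterate","age_ge60","0.350**",0.35,"**",""
"urban","illiterate","loss_labor_ability","0.210",0.21,"",""
"urban","living_alone","age_ge60","-0.040",-0.04,"",""
"urban","living_alone","loss_labor_ability","0.040",0.04,"",""
"urban","living_alone","illiterate","-0.190",-0.19,"",""
"urban","age_ge60_living_alone","age_ge60","0.400**",0.4,"**",""
"urban","age_ge60_living_alone","loss_labor_ability","0.403**",0.403,"**","printed with three decimals (0.403); extra digit retained as printed"
"urban","age_ge60_living_alone","illiterate","0.060",0.06,"",""
"urban","age_ge60_living_alone","living_alone","0.450**",0.45,"**",""
"urban","low_income","age_ge60","0.020",0.02,"",""
"urban","low_income","loss_labor_ability","-0.120",-0.12,"",""
"urban","low_income","illiterate","0.210",0.21,"",""
"urban","low_income","living_alone","-0.150",-0.15,"",""
"urban","low_income","age_ge60_living_alone","-0.110",-0.11,"",""
"urban","low_income_seniors","age_ge60","0.130",0.13,"",""
"urban","low_income_seniors","loss_labor_ability","0.020",0.02,"",""
"urban","low_income_seniors","illiterate","0.190",0.19,"",""
"urban","low_income_seniors","living_alone","-0.100",-0.1,"",""
"urban","low_income_seniors","age_ge60_living_alone","-0.110",-0.11,"",""
"urban","low_income_seniors","low_income","0.680**",0.68,"**",""
"urban","low_income_households","age_ge60","0.110",0.11,"",""
"urban","low_income_households","loss_labor_ability","-0.050",-0.05,"",""
"urban","low_income_households","illiterate","0.270*",0.27,"*",""
"urban","low_income_households","living_alone","-0.310**",-0.31,"**",""
"urban","low_income_households","age_ge60_living_alone","-0.150",-0.15,"",""
"urban","low_income_households","low_income","0.890**",0.89,"**",""
"urban","low_income_households","low_income_seniors","0.740**",0.74,"**",""
"urban","households_one_room","age_ge60","-0.190",-0.19,"",""
"urban","households_one_room","loss_labor_ability","-0.240*",-0.24,"*",""
"urban","households_one_room","illiterate","-0.150",-0.15,"",""
"urban","households_one_room","living_alone","0.270*",0.27,"*",""
"urban","households_one_room","age_ge60_living_alone","-0.040",-0.04,"",""
"urban","households_one_room","low_income","-0.160",-0.16,"",""
"urban","households_one_room","low_income_seniors","-0.350**",-0.35,"**",""
"urban","households_one_room","low_income_households","-0.350**",-0.35,"**",""
"urban","households_le8m2","age_ge60","-0.080",-0.08,"",""
"urban","households_le8m2","loss_labor_ability","-0.130",-0.13,"",""
"urban","households_le8m2","illiterate","-0.120",-0.12,"",""
"urban","households_le8m2","living_alone","-0.040",-0.04,"",""
"urban","households_le8m2","age_ge60_living_alone","0.020",0.02,"",""
"urban","households_le8m2","low_income","-0.070",-0.07,"",""
"urban","households_le8m2","low_income_seniors","-0.200",-0.2,"",""
"urban","households_le8m2","low_income_households","-0.220",-0.22,"",""
"urban","households_le8m2","households_one_room","0.630**",0.63,"**",""
"rural","loss_labor_ability","age_ge60","0.040**",0.04,"**","starred p<=0.01 but r=0.04 is inconsistent at n=73; suspected misprint; recorded as printed"
"rural","illiterate","age_ge60","-0.300**",-0.3,"**",""
"rural","illiterate","loss_labor_ability","-0.280*",-0.28,"*",""
"rural","living_alone","age_ge60","0.020",0.02,"",""
"rural","living_alone","loss_labor_ability","0.220",0.22,"",""
"rural","living_alone","illiterate","-0.240*",-0.24,"*",""
"rural","age_ge60_living_alone","age_ge60","0.130",0.13,"",""
"rural","age_ge60_living_alone","loss_labor_ability","0.190",0.19,"",""
"rural","age_ge60_living_alone","illiterate","0.060",0.06,"",""
"rural","age_ge60_living_alone","living_alone","0.750**",0.75,"**",""
"rural","low_income","age_ge60","0.160",0.16,"",""
"rural","low_income","loss_labor_ability","-0.160",-0.16,"",""
"rural","low_income","illiterate","0.130",0.13,"",""
"rural","low_income","living_alone","-0.150",-0.15,"",""
"rural","low_income","age_ge60_living_alone","0.050",0.05,"",""
"rural","low_income_seniors","age_ge60","-0.030",-0.03,"",""
"rural","low_income_seniors","loss_labor_ability","-0.100",-0.1,"",""
"rural","low_income_seniors","illiterate","-0.060",-0.06,"",""
"rural","low_income_seniors","living_alone","-0.080",-0.08,"",""
"rural","low_income_seniors","age_ge60_living_alone","-0.020",-0.02,"",""
"rural","low_income_seniors","low_income","0.690**",0.69,"**",""
"rural","low_income_households","age_ge60","0.230*",0.23,"*",""
"rural","low_income_households","loss_labor_ability","0.030",0.03,"",""
"rural","low_income_households","illiterate","0.070",0.07,"",""
"rural","low_income_households","living_alone","-0.160",-0.16,"",""
"rural","low_income_households","age_ge60_living_alone","0.020",0.02,"",""
"rural","low_income_households","low_income","0.590**",0.59,"**",""
"rural","low_income_households","low_income_seniors","0.390**",0.39,"**",""
"rural","households_one_room","age_ge60","-0.360**",-0.36,"**",""
"rural","households_one_room","loss_labor_ability","-0.210",-0.21,"",""
"rural","households_one_room","illiterate","0.380**",0.38,"**",""
"rural","households_one_room","living_alone","0.350**",0.35,"**",""
"rural","households_one_room","age_ge60_living_alone","0.340**",0.34,"**",""
"rural","households_one_room","low_income","-0.330**",-0.33,"**",""
"rural","households_one_room","low_income_seniors","-.30**",-0.3,"**","printed without leading zero (-.30)"
"rural","households_one_room","low_income_households","-0.270*",-0.27,"*",""
"rural","households_le8m2","age_ge60","-0.180",-0.18,"",""
"rural","households_le8m2","loss_labor_ability","-0.230*",-0.23,"*",""
"rural","households_le8m2","illiterate","0.330**",0.33,"**",""
"rural","households_le8m2","living_alone","0.240*",0.24,"*",""
"rural","households_le8m2","age_ge60_living_alone","0.260*",0.26,"*",""
"rural","households_le8m2","low_income","-0.250*",-0.25,"*",""
"rural","households_le8m2","low_income_seniors","-0.250*",-0.25,"*",""
"rural","households_le8m2","low_income_households","-0.100",-0.1,"",""
"rural","households_le8m2","households_one_room","0.740**",0.74,"**",""
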