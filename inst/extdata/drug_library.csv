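"drug","Kmax","Ku","n","EC50","Vhalf_trap","provenance"
"dofetilide",1e+08,1.79e-05,0.9831,1730582810,-1.147,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM | alias: example drug T (trapped)"
"verapamil",46460,0.0007927,1.043,4742041.653,-100,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM | alias: example drug N (non-trapped)"
"quinidine",5770,0.01,0.8311,16570966.99,-64.87,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"bepridil",37350000,0.0001765,0.9365,2142795447,-54.93,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"sotalol",2403,0.001985,0.7516,1954425224,-55,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"chlorpromazine",206000,0.03866,0.8871,550775949.9,-14.57,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"cisapride",9.997,0.0004161,0.9728,46.69533632,-199.5,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"terfenadine",9884,8.18e-05,0.65,12669357.59,-77.49,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"ondansetron",33540,0.02325,0.8874,76870483.59,-82.11,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"diltiazem",251,0.2816,0.9485,2117276.335,-90.89,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"mexiletine",99960000,0.09967,1.304,15149404.29,-86.26,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
"ranolazine",55.84,0.01929,0.95,276739.8888,-94.87,"CiPA dynamic hERG binding model, 37C parameter set (Li et al. 2017, FDA CiPA implementation); EC50 = halfmax^(1/n) of the original table, nM"
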