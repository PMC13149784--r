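process,wake_pct,nrem_pct,rem_pct,total_smr_pct,state_uncertainty,smr_uncertainty
Ion regulation (brain),50,15,35,15,Moderate,Low
Ion regulation (peripheral),60,35,5,12,Moderate,Moderate
Protein synthesis,10,60,30,18,Low,Low
Immune surveillance,25,60,15,7,Moderate,High
Thermoregulation,70,25,5,15,Low,Moderate
Neural plasticity,20,45,35,4,Low,Moderate
Sensory processing,90,5,5,5,Low,Moderate
Glymphatic metabolic clearance,30,60,10,5,Low,High
Nitrogenous waste processing,45,35,20,2,Moderate,Low
Substrate cycling,60,20,20,7,Moderate,Low
Gluconeogenesis,35,60,5,4,High,Low
Residual background processes,33,33,33,6,Moderate,Moderate
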