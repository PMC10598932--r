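pdo,drug,auc_score,sensitivity_score,final_score,hit
ORG001,Oxaliplatin,1.8,0.8,2.6,TRUE
ORG002,5FU,1.4,0.7,2.1,TRUE
ORG003,Gemcitabine,2.5,0.9,3.4,TRUE
ORG004,Paclitaxel,0.9,0.3,1.2,FALSE
ORG005,Docetaxel,1.7,0.6,2.3,TRUE
ORG006,Oxaliplatin,1.2,0.3,1.5,FALSE
ORG007,Pemetrexed,0.8,0.1,0.9,FALSE
ORG008,5FU,0.95,0.15,1.1,FALSE
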