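patient,pdo,drug,best_response
PAT001,ORG001,Oxaliplatin,PR
PAT002,ORG002,5FU,SD
PAT003,ORG003,Gemcitabine,PR
PAT004,ORG004,Paclitaxel,SD
PAT005,ORG005,Docetaxel,PD
PAT006,ORG006,Oxaliplatin,PD
PAT007,ORG007,Pemetrexed,PD
PAT008,ORG008,5FU,PD
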