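adr_term,soc
Nausea,Gastrointestinal disorders
Vomiting,Gastrointestinal disorders
Diarrhoea,Gastrointestinal disorders
Myelosuppression,Blood and lymphatic system disorders
Leukopenia,Blood and lymphatic system disorders
Anaemia,Blood and lymphatic system disorders
Rash,Skin and subcutaneous tissue disorders
Urticaria,Skin and subcutaneous tissue disorders
Pruritus,Skin and subcutaneous tissue disorders
High aminotransferase,Investigations
Blood pressure increased,Investigations
Fever,General disorders and administration site conditions
Chills,General disorders and administration site conditions
Fatigue,General disorders and administration site conditions
Headache,Nervous system disorders
Dizziness,Nervous system disorders
Dyspnea,"Respiratory, thoracic, and mediastinal disorders"
Pneumonitis,"Respiratory, thoracic, and mediastinal disorders"
Cough,"Respiratory, thoracic, and mediastinal disorders"
Hypertension,Vascular disorders
Phlebitis,Vascular disorders
Myalgia,Musculoskeletal and connective tissue disorders
Arthralgia,Musculoskeletal and connective tissue disorders
Palpitations,Cardiac disorders
Chest discomfort,Cardiac disorders
Hepatic failure,Hepatobiliary disorders
Liver injury,Hepatobiliary disorders
Decreased appetite,Metabolism and nutrition disorders
Hypokalaemia,Metabolism and nutrition disorders
Anaphylactoid reaction,Immune system disorders
Hypersensitivity,Immune system disorders
Haematuria,Renal and urinary disorders
Renal impairment,Renal and urinary disorders
Hyperthyroidism,Endocrine disorders
Hypothyroidism,Endocrine disorders
Insomnia,Psychiatric disorders
Anxiety,Psychiatric disorders
Conjunctivitis,Eye disorders
Vision blurred,Eye disorders
Infusion related reaction,"Injury, poisoning, and procedural complications"
Haemangioma,"Neoplasms benign, malignant, and unspecified (including cysts and polyps)"
Tinnitus,Ear and labyrinth disorders
Pneumonia,Infections and infestations
Breast pain,Reproductive system and breast disorders
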