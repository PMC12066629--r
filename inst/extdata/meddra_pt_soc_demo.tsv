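pt	soc
Hypoglycaemia	Metabolism And Nutrition Disorders
Hyperglycaemia	Metabolism And Nutrition Disorders
Diabetic Ketoacidosis	Metabolism And Nutrition Disorders
Insulin Resistance	Metabolism And Nutrition Disorders
Decreased Appetite	Metabolism And Nutrition Disorders
Injection Site Pain	General Disorders And Administration Site Conditions
Injection Site Haemorrhage	General Disorders And Administration Site Conditions
Injection Site Bruising	General Disorders And Administration Site Conditions
Fatigue	General Disorders And Administration Site Conditions
Pyrexia	General Disorders And Administration Site Conditions
Visual Impairment	Eye Disorders
Cataract	Eye Disorders
Blindness	Eye Disorders
Diabetic Retinopathy	Eye Disorders
Headache	Nervous System Disorders
Dizziness	Nervous System Disorders
Memory Impairment	Nervous System Disorders
Cerebrovascular Accident	Nervous System Disorders
Nausea	Gastrointestinal Disorders
Vomiting	Gastrointestinal Disorders
Diarrhoea	Gastrointestinal Disorders
Abdominal Pain	Gastrointestinal Disorders
Rash	Skin And Subcutaneous Tissue Disorders
Pruritus	Skin And Subcutaneous Tissue Disorders
Lipodystrophy Acquired	Skin And Subcutaneous Tissue Disorders
Myocardial Infarction	Cardiac Disorders
Palpitations	Cardiac Disorders
Nasopharyngitis	Infections And Infestations
Pneumonia	Infections And Infestations
Pancreatic Neoplasm	Neoplasms Benign, Malignant And Unspecified (Incl Cysts And Polyps)
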