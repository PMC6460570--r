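code	group	requires_confirmation	description
T88.6	allergy_hypersensitivity	FALSE	Anaphylactic shock due to adverse effect of correct drug properly administered
T88.7	allergy_hypersensitivity	FALSE	Unspecified adverse effect of drug or medicament
T80.6	allergy_hypersensitivity	FALSE	Other serum reactions
Z88.0	allergy_hypersensitivity	FALSE	Allergy status to penicillin
Z88.1	allergy_hypersensitivity	FALSE	Allergy status to other antibiotic agents
Z88.8	allergy_hypersensitivity	FALSE	Allergy status to other drugs and biological substances
Z88.9	allergy_hypersensitivity	FALSE	Allergy status to unspecified drugs and biological substances
L23.3	dermatologic	FALSE	Allergic contact dermatitis due to drugs in contact with skin
L24.4	dermatologic	FALSE	Irritant contact dermatitis due to drugs in contact with skin
L25.1	dermatologic	FALSE	Unspecified contact dermatitis due to drugs in contact with skin
L27.0	dermatologic	FALSE	Generalized skin eruption due to drugs and medicaments
L27.1	dermatologic	FALSE	Localized skin eruption due to drugs and medicaments
L43.2	dermatologic	FALSE	Lichenoid drug reaction
L56.0	dermatologic	FALSE	Drug phototoxic response
L56.1	dermatologic	FALSE	Drug photoallergic response
L64.0	dermatologic	FALSE	Drug-induced androgenic alopecia
L10.5	dermatologic	FALSE	Drug-induced pemphigus
G72.0	myopathy	FALSE	Drug-induced myopathy
M60.9	myopathy	TRUE	Myositis, unspecified
M60.8	myopathy	TRUE	Other myositis
M62.8	myopathy	TRUE	Other specified disorders of muscle
M79.1	myopathy	TRUE	Myalgia
M10.2	myopathy	FALSE	Drug-induced gout
K71.0	hepatic	FALSE	Toxic liver disease with cholestasis
K71.1	hepatic	FALSE	Toxic liver disease with hepatic necrosis
K71.2	hepatic	FALSE	Toxic liver disease with acute hepatitis
K71.6	hepatic	FALSE	Toxic liver disease with hepatitis, not elsewhere classified
K71.9	hepatic	FALSE	Toxic liver disease, unspecified
R74.0	hepatic	TRUE	Elevation of levels of transaminase and lactic acid dehydrogenase
N14.0	renal	FALSE	Analgesic nephropathy
N14.1	renal	FALSE	Nephropathy induced by other drugs, medicaments and biological substances
N14.2	renal	FALSE	Nephropathy induced by unspecified drug, medicament or biological substance
N14.3	renal	FALSE	Nephropathy induced by heavy metals
N14.4	renal	FALSE	Toxic nephropathy, not elsewhere classified
N17.9	renal	TRUE	Acute kidney failure, unspecified
D59.0	hematologic	FALSE	Drug-induced autoimmune haemolytic anaemia
D59.2	hematologic	FALSE	Drug-induced nonautoimmune haemolytic anaemia
D61.1	hematologic	FALSE	Drug-induced aplastic anaemia
D64.2	hematologic	FALSE	Secondary sideroblastic anaemia due to drugs and toxins
D69.5	hematologic	TRUE	Secondary thrombocytopenia
D70	hematologic	TRUE	Agranulocytosis
E03.2	endocrine_metabolic	FALSE	Hypothyroidism due to medicaments and other exogenous substances
E06.4	endocrine_metabolic	FALSE	Drug-induced thyroiditis
E16.0	endocrine_metabolic	FALSE	Drug-induced hypoglycaemia without coma
E23.1	endocrine_metabolic	FALSE	Drug-induced hypopituitarism
E24.2	endocrine_metabolic	FALSE	Drug-induced Cushing's syndrome
E27.3	endocrine_metabolic	FALSE	Drug-induced adrenocortical insufficiency
E66.1	endocrine_metabolic	FALSE	Drug-induced obesity
G21.1	neurologic_movement	FALSE	Other drug-induced secondary parkinsonism
G24.0	neurologic_movement	FALSE	Drug-induced dystonia
G25.1	neurologic_movement	FALSE	Drug-induced tremor
G25.4	neurologic_movement	FALSE	Drug-induced chorea
G25.6	neurologic_movement	FALSE	Drug-induced tics and other tics of organic origin
G25.7	neurologic_movement	FALSE	Other and unspecified drug-induced movement disorders
G44.4	neurologic_movement	FALSE	Drug-induced headache, not elsewhere classified
G62.0	neurologic_movement	FALSE	Drug-induced polyneuropathy
I42.7	cardiovascular	FALSE	Cardiomyopathy due to drugs and other external agents
I95.2	cardiovascular	FALSE	Hypotension due to drugs
I49.9	cardiovascular	TRUE	Cardiac arrhythmia, unspecified
R00.1	cardiovascular	TRUE	Bradycardia, unspecified
J70.2	respiratory	FALSE	Acute drug-induced interstitial lung disorders
J70.3	respiratory	FALSE	Chronic drug-induced interstitial lung disorders
J70.4	respiratory	FALSE	Drug-induced interstitial lung disorders, unspecified
J70.8	respiratory	FALSE	Respiratory conditions due to other specified external agents
J70.9	respiratory	FALSE	Respiratory conditions due to unspecified external agent
K85.3	gastrointestinal	FALSE	Drug-induced acute pancreatitis
K52.1	gastrointestinal	FALSE	Toxic gastroenteritis and colitis
K25.9	gastrointestinal	TRUE	Gastric ulcer, unspecified
K29.7	gastrointestinal	TRUE	Gastritis, unspecified
K92.2	gastrointestinal	TRUE	Gastrointestinal haemorrhage, unspecified
K30	gastrointestinal	TRUE	Functional dyspepsia
K59.0	gastrointestinal	TRUE	Constipation
K52.9	gastrointestinal	TRUE	Noninfective gastroenteritis and colitis, unspecified
F05.8	psychiatric	TRUE	Other delirium
F05.9	psychiatric	TRUE	Delirium, unspecified
F19.9	psychiatric	TRUE	Mental disorder due to multiple drug use, unspecified
F13.9	psychiatric	TRUE	Mental disorder due to use of sedatives or hypnotics, unspecified
F15.9	psychiatric	TRUE	Mental disorder due to use of other stimulants, unspecified
F11.9	psychiatric	TRUE	Mental disorder due to use of opioids, unspecified
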