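key	vt_term	display_name
cholesterol	VT:0000180	Cholesterol
creatinine	VT:0005328	Creatinine
glucose	VT:0000188	Glucose
total_protein	VT:0005567	Total protein
triglycerides	VT:0002644	Triglycerides
urea	VT:0005265	Urea
uric_acid	VT:0010302	Uric acid
ferritin	VT:0010513	Ferritin
transferrin	VT:0010514	Transferrin
calcium	VT:0001562	Calcium
chloride	VT:0003018	Chloride
phosphorus	VT:0001565	Phosphorus
potassium	VT:0002668	Potassium
sodium	VT:0001776	Sodium
alt	VT:0001573	ALT
ast	VT:0000203	AST
alpha_amylase	VT:0010475	alpha-Amylase
ap	VT:0000202	Alkaline phosphatase
ck	VT:1000047	Creatine kinase
lipase	VT:0010478	Lipase
hemoglobin	VT:0001588	Hemoglobin
mcv		MCV
rbc	VT:0001586	RBC
wbc	VT:0000217	WBC
platelets	VT:0003179	Platelets
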