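drug	atc1
AMLODIPINE	C
METFORMIN	A
ASPIRIN	B
ATORVASTATIN	C
LISINOPRIL	C
OMEPRAZOLE	A
LEVOTHYROXINE	H
SIMVASTATIN	C
LOSARTAN	C
GABAPENTIN	N
HYDROCHLOROTHIAZIDE	C
SERTRALINE	N
FUROSEMIDE	C
METOPROLOL	C
PANTOPRAZOLE	A
PREDNISONE	H
IBUPROFEN	M
AMOXICILLIN	J
WARFARIN	B
INSULIN GLARGINE	A
CLOPIDOGREL	B
FLUOXETINE	N
TRAMADOL	N
DULOXETINE	N
RAMIPRIL	C
CIPROFLOXACIN	J
QUETIAPINE	N
CELECOXIB	M
ESOMEPRAZOLE	A
RIVAROXABAN	B
LEVOFLOXACIN	J
PARACETAMOL	N
BISOPROLOL	C
ROSUVASTATIN	C
VENLAFAXINE	N
CITALOPRAM	N
ALLOPURINOL	M
SPIRONOLACTONE	C
DIGOXIN	C
AMIODARONE	C
RISPERIDONE	N
OLANZAPINE	N
ESCITALOPRAM	N
LANSOPRAZOLE	A
MONTELUKAST	R
SALBUTAMOL	R
TIOTROPIUM	R
DICLOFENAC	M
NAPROXEN	M
MORPHINE	N
OXYCODONE	N
FENTANYL	N
ONDANSETRON	A
METHOTREXATE	L
ADALIMUMAB	L
ETANERCEPT	L
RITUXIMAB	L
BEVACIZUMAB	L
TRASTUZUMAB	L
PEMBROLIZUMAB	L
NIVOLUMAB	L
PACLITAXEL	L
DOCETAXEL	L
CISPLATIN	L
CARBOPLATIN	L
ANASTROZOLE	L
LETROZOLE	L
TAMOXIFEN	L
VANCOMYCIN	J
CEFTRIAXONE	J
MEROPENEM	J
AZITHROMYCIN	J
CLARITHROMYCIN	J
DOXYCYCLINE	J
SULFAMETHOXAZOLE/TRIMETHOPRIM	J
FLUCONAZOLE	J
POSACONAZOLE	J
AMPHOTERICIN B	J
ACICLOVIR	J
OSELTAMIVIR	J
ENOXAPARIN	B
HEPARIN	B
APIXABAN	B
DABIGATRAN	B
TICAGRELOR	B
CARBAMAZEPINE	N
LAMOTRIGINE	N
LEVETIRACETAM	N
VALPROATE	N
PHENYTOIN	N
LORAZEPAM	N
DIAZEPAM	N
ZOLPIDEM	N
LITHIUM	N
CIMETIDINE	A
RANITIDINE	A
SITAGLIPTIN	A
EMPAGLIFLOZIN	A
LIRAGLUTIDE	A
HYDROXYCHLOROQUINE	P
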