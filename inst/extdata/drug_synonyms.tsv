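raw	standard
METFORMIN HCL	METFORMIN
METFORMIN HYDROCHLORIDE	METFORMIN
ACETYLSALICYLIC ACID	ASPIRIN
ASA	ASPIRIN
ACETAMINOPHEN	PARACETAMOL
TYLENOL	PARACETAMOL
LASIX	FUROSEMIDE
COUMADIN	WARFARIN
GLUCOPHAGE	METFORMIN
NORVASC	AMLODIPINE
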