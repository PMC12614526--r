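country	region
US	North America
CA	North America
MX	North America
FR	Europe
GB	Europe
DE	Europe
IT	Europe
ES	Europe
NL	Europe
SE	Europe
CH	Europe
BE	Europe
PL	Europe
PT	Europe
JP	Asia
CN	Asia
IN	Asia
KR	Asia
TW	Asia
TH	Asia
BR	South America
AR	South America
CO	South America
CL	South America
PE	South America
AU	Oceania
NZ	Oceania
ZA	Africa
NG	Africa
EG	Africa
KE	Africa
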