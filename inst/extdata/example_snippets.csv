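snippet_id,key_phrase,text,label,expected_method
ex01,substance abuse,"substance abuse treatment heroin last used: ""yesterday""",positive,ml
ex02,opioid dependence,"4. low back pain 5. opioid dependence 6. homeless single person",positive,rule
ex03,opioid dependence,"opioid dependence (icd-9-cm 304.00)",positive,rule
ex04,opiate,"alludes to the possibility of self medicating on the street opiate withdrawal",positive,ml
ex05,morphine,"would not receive prescription for morphine and oxycodone until next month reiterated multiple times that taking additional doses of opiates was a patient safety issue and would not be tolerated",positive,ml
ex06,opioid dependence,"allergies: darvon, periactin, phenothiazine/related antipsychotics, demerol opioid dependence (icd-9-cm 304.00)",positive,rule
ex07,lorcet,"pt has pain mostly at night was on lorcet and tried to change to morphine but since she developed rash",negative,ml
ex08,hydromorphone,"hydromorphone 4 mg tab take one tablet every four active hours when needed for pain",negative,rule
ex09,substance abuse,"family hx of substance abuse",negative,rule
ex10,lortab,"patient requested no lortab",negative,ml
ex11,oxycodone,"continue tylenol and oxycodone as needed per home regimen",negative,ml
ex12,hydromorphone,"9) hydromorphone inj, soln active give: 0.5 mg/0.5 ml ivp q2h prn for pain",negative,rule
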