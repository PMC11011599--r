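# Key-phrase lexicon: one phrase per line, optional tab-separated category
# (drug_name = generic/trade opioid name, other = concept phrase).
abstral	drug_name
actiq	drug_name
demerol	drug_name
dilaudid	drug_name
dolophine	drug_name
duragesic	drug_name
exalgo	drug_name
fentanyl	drug_name
fentora	drug_name
hydrocodone	drug_name
hydromorphone	drug_name
hysingla	drug_name
kadian	drug_name
lorcet	drug_name
lortab	drug_name
meperidine	drug_name
methadone	drug_name
methadose	drug_name
morphine	drug_name
norco	drug_name
oxaydo	drug_name
oxycodone	drug_name
oxycontin	drug_name
percocet	drug_name
roxicet	drug_name
vicodin	drug_name
zohydro	drug_name
dependence	other
opiate	other
opiate abuse	other
opioid	other
opioid dependence	other
polysubstance abuse	other
substance abuse	other
substance dependence	other
withdrawal	other
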