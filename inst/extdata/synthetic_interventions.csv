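label,synonyms,group,case_sensitive
donepezil,Aricept,cholinergic system,
galantamine,,cholinergic system,
rivastigmine,,cholinergic system,
tacrine,,cholinergic system,
huperzine A,,cholinergic system,
memantine,,glutamatergic system,
lithium,lithium chloride,kinase signalling,
rapamycin,sirolimus,autophagy,
minocycline,,anti-inflammatory,
ibuprofen,,anti-inflammatory,
curcumin,,dietary compound,
resveratrol,,dietary compound,
melatonin,,hormonal,
insulin,intranasal insulin,metabolic,
lecanemab,,immunotherapy,
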