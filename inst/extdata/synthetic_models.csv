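label,synonyms,group,case_sensitive
APP/PS1,APPswe/PSEN1dE9|APP/PSEN1,amyloid transgenic,
5xFAD,5XFAD mice line,amyloid transgenic,
3xTg-AD,triple transgenic,combined pathology,
Tg2576,,amyloid transgenic,
TgCRND8,,amyloid transgenic,
J20,hAPP-J20,amyloid transgenic,
PDAPP,,amyloid transgenic,
rTg4510,,tau transgenic,
PS19,,tau transgenic,
hTau,,tau transgenic,
SAMP8,senescence-accelerated prone 8,accelerated senescence,
ApoE4-TR,ApoE4 targeted replacement,risk-factor model,
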