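label,synonyms,group,case_sensitive
mouse,mice|murine,,
rat,rats,,
zebrafish,danio rerio,,
drosophila,fruit fly,,
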