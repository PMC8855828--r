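variant,severity_years,is_null
null,6.88,TRUE
p.Gly1961Glu,34.63,FALSE
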