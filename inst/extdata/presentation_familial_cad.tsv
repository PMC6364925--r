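presentation	count
STEMI	254
NSTEMI	88
UAP	51
SAP	268
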