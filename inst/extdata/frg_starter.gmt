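FRG_positive	positive ferroptosis regulators (printed panel)	LPCAT3	NCOA4	ACSL4	GPX4	SLC3A2	ALOX15	SLC7A11	NOX5	NFE2L2	NOX3	NOX1	NOX4
FRG_negative	negative ferroptosis regulators (partial printed list)	FDFT1	COQ10A	HMGCR	COQ10B
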