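# Keratins characteristic of hair, skin/epidermis, tongue and gums:
# highly probable co-IP contaminants.
KRT33A
KRT78
KRT85
KRT14
KRT5
KRT3
KRT31
KRT32
KRT33B
KRT35
KRT36
KRT4
KRT77
KRT8
KRT17
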