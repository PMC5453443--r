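motif_id	sequence	category	source
CCA1	AAAAATCT	circadian	publication
morning_element	CCACAC	circadian	publication
evening_element	TGGATA	circadian	publication
PRE	ACTCAT	proline_hypoosmolarity	publication
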