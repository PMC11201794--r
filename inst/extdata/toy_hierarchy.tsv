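child_id	parent_id
R-TOY-02	R-TOY-01
R-TOY-01	IMMUNE_SYSTEM
R-TOY-03	IMMUNE_SYSTEM
R-TOY-04	SIGNAL_TRANSDUCTION
R-TOY-05	CELLULAR_RESPONSES_TO_STIMULI
R-TOY-06	CELL_CYCLE
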