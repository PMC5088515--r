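x_start	x_end	y_start	y_end	strand
748012	749513	746988	748493	f
762953	764494	761936	763425	f
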