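x_start	x_end	y_start	y_end	strand
711591	747965	710528	746902	f
749573	762895	761860	748534	r
764581	780474	763521	779414	f
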