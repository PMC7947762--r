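model	marker	trusted_cutoff
TIGR01289	LPOR	200.0
TIGR02014	BchB	250.0
TIGR02016	BchL	230.0
TIGR02015	BchN	240.0
PF00016	RuBisCO_large	100.0
PF00485	PRK	100.0
TIGR02026	BchE	300.0
TIGR02029	AcsF	220.0
TIGR01157	PufL	180.0
TIGR01115	PufM	180.0
PF00223	PsaA	150.0
PF00124	PsaB	150.0
PF00421	PsbA	150.0
PF00422	PsbD	150.0
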