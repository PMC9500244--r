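GATA4	MYH6	Activation	synthetic-fixture
GATA4	MYH7	Activation	synthetic-fixture
NKX2-5	MYH6	Activation	synthetic-fixture
STAT3	SOCS1	Activation	synthetic-fixture
JAK2	STAT3	Activation	synthetic-fixture
TP53	JAK2	Repression	synthetic-fixture
CEBPD	SOCS1	Unknown	synthetic-fixture
SP1	TKT	Activation	synthetic-fixture
MYC	TKT	Activation	synthetic-fixture
EGR1	ZFP36	Activation	synthetic-fixture
HIF1A	DDIT3	Activation	synthetic-fixture
ATF4	DDIT3	Activation	synthetic-fixture
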