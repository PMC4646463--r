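# Default literature prior network over the molecule nodes (editable).
# Format: parent<TAB>-><TAB>child, one directed edge per line.
EGFR	->	ERK
EGFR	->	AKT
EGFR	->	p38
ERK	->	CREB
ERK	->	JUN
ERK	->	p70S6K
p38	->	CREB
p38	->	JUN
AKT	->	CREB
AKT	->	p70S6K
p70S6K	->	RPS6
ERK	->	GLI1
ERK	->	GLI2
AKT	->	GLI1
SHH	->	PTCH1
PTCH1	->	GLI1
PTCH1	->	GLI2
HHIP	->	GLI1
HHIP	->	GLI2
GLI2	->	GLI1
GLI1	->	PTCH1
GLI1	->	HHIP
GLI2	->	PTCH1
GLI2	->	HHIP
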