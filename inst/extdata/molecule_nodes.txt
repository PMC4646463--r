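# Default molecule node set (13 signalling molecules, editable).
# One identifier per line; lines starting with '#' are ignored.
EGFR
ERK
AKT
p38
CREB
JUN
p70S6K
RPS6
SHH
PTCH1
HHIP
GLI1
GLI2
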