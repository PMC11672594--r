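# Hemiketal formation, path 1: PKS-assisted olefin shift, then cyclization.
# Stage free energies in kcal/mol; barriers are TS heights above the
# preceding minimum (the printed barriers do not state their reference;
# see ts_reference in the loaded object). provenance: printed | derived
from	to	delta_g	barrier	ts_label	provenance
R	1	-2.9	NA	NA	printed
1	P	-6.84	31.6	TS1	printed
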