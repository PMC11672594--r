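# Hemiketal formation, path 2: 6-pi-electrocyclization of the triene,
# then water addition. Stage free energies in kcal/mol; barriers are TS
# heights above the preceding minimum. The 2->P stage is not printed and
# is solved from the printed overall (-4.2) by telescoping.
from	to	delta_g	barrier	ts_label	provenance
R	1	2.45	NA	NA	printed
1	2	-1.76	25.6	TS1	printed
2	P	-4.89	35	TS2	derived
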