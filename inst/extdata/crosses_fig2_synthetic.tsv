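# Synthetic cross-design table: the 13 hybrid ids are real; only the
# parentages of 17H39 (E103 x PDLUC) and 17H57 (E103 x E111) are printed in
# the source text. The remaining parent pairs are synthetic assignments,
# chosen to be consistent with each hybrid's printed marker calls given the
# parental calls.
hybrid_id	parent1_id	parent2_id
17H14	PDVIT	E7
17H25	E11	LA3120
17H36	E103	E42
17H37	E103	E36
17H39	E103	PDLUC
17H56	PDVIT	E45
17H57	E103	E111
18H13	E42	LA2662
18H17	E109	LA3120
18H48	E11	E48
18H56	E11	E20
18H57	E109	E7
18H59	E42	E109
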