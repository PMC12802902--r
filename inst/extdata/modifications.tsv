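name	delta_mass	targets	class
Acetyl (Protein N-term)	42.010565	N-term	biological
Acetyl (K)	42.010565	K	biological
Acetyl (S)	42.010565	S	biological
Acetyl (T)	42.010565	T	biological
Phospho (S)	79.966331	S	biological
Phospho (T)	79.966331	T	biological
Phospho (Y)	79.966331	Y	biological
Methyl (K)	14.015650	K	biological
Dimethyl (K)	28.031300	K	biological
Trimethyl (K)	42.046950	K	biological
Methyl (R)	14.015650	R	biological
Dimethyl (R)	28.031300	R	biological
Methyl (H)	14.015650	H	biological
Methyl (E)	14.015650	E	biological
Hydroxylation (P)	15.994915	P	biological
Hydroxylation (K)	15.994915	K	biological
Propionyl (K)	56.026215	K	biological
Butyryl (K)	70.041865	K	biological
Lactyl (K)	72.021129	K	biological
Crotonyl (K)	68.026215	K	biological
Succinyl (K)	100.016044	K	biological
Malonyl (K)	86.000394	K	biological
Glutaryl (K)	114.031694	K	biological
GlyGly (K)	114.042927	K	biological
Citrullination (R)	0.984016	R	biological
Formyl (K)	27.994915	K	biological
2-Hydroxyisobutyryl (K)	86.036779	K	biological
Oxidation (M)	15.994915	M	post_isolation
Oxidation (W)	15.994915	W	post_isolation
Dioxidation (M)	31.989829	M	post_isolation
Dioxidation (W)	31.989829	W	post_isolation
Deamidation (N)	0.984016	N	post_isolation
Deamidation (Q)	0.984016	Q	post_isolation
Carbamidomethyl (C)	57.021464	C	post_isolation
Carbamyl (N-term)	43.005814	N-term	post_isolation
Carbamyl (K)	43.005814	K	post_isolation
Gln->pyro-Glu (N-term Q)	-17.026549	N-term,Q	post_isolation
Glu->pyro-Glu (N-term E)	-18.010565	N-term,E	post_isolation
Formyl (N-term)	27.994915	N-term	post_isolation
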