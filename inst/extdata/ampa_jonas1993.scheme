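# 7-state AMPA receptor kinetic scheme.
# States C0..C5 are closed (C3..C5 desensitized), O conducts.
# Rate constants from Jonas, Major & Sakmann (1993), J Physiol 472:615-663,
# as reproduced in numerous synaptic modeling studies.
# Units: ligand_order 0 -> 1/s; ligand_order 1 -> 1/(M s).
name ampa_jonas1993
state C0 0
state C1 1
state C2 2
state C3 1
state C4 2
state C5 2
state O 2 open
initial C0
transition C0 C1 4.59e6 1
transition C1 C0 4.26e3 0
transition C1 C2 2.84e7 1
transition C2 C1 3.26e3 0
transition C2 O 4.24e3 0
transition O C2 9.00e2 0
transition C1 C3 2.89e3 0
transition C3 C1 3.92e1 0
transition C3 C4 1.27e6 1
transition C4 C3 4.57e1 0
transition C2 C4 1.72e2 0
transition C4 C2 7.27e-1 0
transition C4 C5 1.68e1 0
transition C5 C4 1.904e2 0
transition O C5 1.77e1 0
transition C5 O 4.0e0 0
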