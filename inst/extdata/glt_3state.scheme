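# Simplified 3-state glutamate transporter cycle: free (T0), glutamate-bound
# (TB), translocating (TT). Binding/unbinding and transport rates in the range
# reported for glial glutamate transporters (cf. Franks, Bartol & Sejnowski
# 2002, Biophys J 83:2333-2348). The TB -> TT step carries the bound glutamate
# into the cell and is flagged as consuming it.
# Units: ligand_order 0 -> 1/s; ligand_order 1 -> 1/(M s).
name glt_3state
state T0 0
state TB 1
state TT 0
initial T0
transition T0 TB 1.8e7 1
transition TB T0 1.8e2 0
transition TB TT 1.8e2 0 consumes
transition TT T0 2.57e1 0
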