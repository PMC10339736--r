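# Standard synthetic-reference fixture set, version 1.
# Regenerated in code from (seed, sizes, gap_min, sigma); never downloaded.
# suite: perturbative -> CIS(D)-type oracle-equivalence fixtures;
#        iterative    -> ADC(2)-type folded-solver fixtures (kept small so
#                        the dense configuration space stays cheap).
suite	seed	n_occ	n_virt	n_aux	gap_min	sigma
perturbative	101	2	3	12	0.2	0.05
perturbative	102	3	4	15	0.2	0.05
perturbative	103	4	5	18	0.2	0.05
perturbative	104	5	6	20	0.2	0.05
perturbative	105	5	7	24	0.2	0.05
perturbative	106	2	7	16	0.2	0.05
perturbative	107	3	3	10	0.2	0.05
perturbative	108	4	6	20	0.2	0.05
perturbative	109	5	5	15	0.2	0.05
perturbative	110	3	7	22	0.2	0.05
perturbative	111	4	4	14	0.3	0.08
perturbative	112	5	7	25	0.3	0.08
perturbative	113	2	5	12	0.5	0.10
perturbative	114	3	6	18	0.5	0.10
perturbative	115	4	7	21	0.4	0.05
perturbative	116	5	4	16	0.4	0.05
perturbative	117	2	4	25	0.2	0.05
perturbative	118	3	5	11	0.2	0.05
perturbative	119	4	3	13	0.2	0.08
perturbative	120	5	6	24	0.2	0.08
iterative	201	2	3	10	0.3	0.05
iterative	202	3	3	12	0.3	0.05
iterative	203	3	4	14	0.3	0.05
iterative	204	4	4	16	0.3	0.05
iterative	205	4	5	18	0.3	0.05
iterative	206	2	5	12	0.4	0.05
iterative	207	3	5	15	0.4	0.05
iterative	208	4	3	14	0.4	0.05
iterative	209	3	4	20	0.25	0.05
iterative	210	4	5	16	0.25	0.05
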