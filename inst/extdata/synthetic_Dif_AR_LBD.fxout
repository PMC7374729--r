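Synthetic example of the FoldX "Dif" point-mutation output dialect.
Energies (kcal/mol) for four AR-LBD mutants; three replicate models each.
Output type: BuildModel

Pdb	total energy	Backbone Hbond	Sidechain Hbond	Van der Waals	Electrostatics
AR_LBD_I738T_0.pdb	1.3	0.02	0.11	0.95	0.01
AR_LBD_I738T_1.pdb	1.4	0.02	0.12	1.01	0.01
AR_LBD_I738T_2.pdb	1.5	0.03	0.12	1.08	0.02
AR_LBD_W752R_0.pdb	3.5	0.10	0.25	2.61	0.12
AR_LBD_W752R_1.pdb	3.6	0.11	0.24	2.68	0.13
AR_LBD_W752R_2.pdb	3.7	0.11	0.26	2.75	0.13
AR_LBD_C807Y_0.pdb	6.1	0.21	0.33	4.91	0.08
AR_LBD_C807Y_1.pdb	6.2	0.22	0.34	4.97	0.08
AR_LBD_C807Y_2.pdb	6.3	0.22	0.35	5.04	0.09
AR_LBD_L813F_0.pdb	6.2	0.18	0.29	5.12	0.05
AR_LBD_L813F_1.pdb	6.3	0.18	0.30	5.19	0.05
AR_LBD_L813F_2.pdb	6.4	0.19	0.30	5.26	0.06
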