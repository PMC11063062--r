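rule	delta_formula	sign
hydrogenation	H2	1
dehydrogenation	H2	-1
methylation	CH2	1
demethylation	CH2	-1
oxidation	O	1
reduction	O	-1
hydration	H2O	1
dehydration	H2O	-1
amination	NH3	1
deamination	NH3	-1
carbonylation	CO	1
decarbonylation	CO	-1
carboxylation	CO2	1
decarboxylation	CO2	-1
acetylation	C2H2O	1
deacetylation	C2H2O	-1
sulfation	SO3	1
desulfation	SO3	-1
glucuronidation	C6H8O6	1
deglucuronidation	C6H8O6	-1
ethylation	C2H4	1
deethylation	C2H4	-1
phosphorylation	HPO3	1
dephosphorylation	HPO3	-1
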