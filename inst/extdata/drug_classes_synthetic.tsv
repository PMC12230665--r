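drug	class
selpercatinib	RET tyrosine kinase inhibitor
pralsetinib	RET tyrosine kinase inhibitor
cabozantinib	VEGFR inhibitor
vandetanib	VEGFR inhibitor
dabrafenib	BRAF inhibitor
vemurafenib	BRAF inhibitor
trametinib	MEK inhibitor
sotorasib	KRAS G12C inhibitor
adagrasib	KRAS G12C inhibitor
osimertinib	EGFR tyrosine kinase inhibitor
erlotinib	EGFR tyrosine kinase inhibitor
cetuximab	anti-EGFR antibody
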