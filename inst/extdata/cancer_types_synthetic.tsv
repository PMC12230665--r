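label	main_type	synonyms
Lung Adenocarcinoma	Lung	LUAD;Adenocarcinoma of the Lung
Non-Small Cell Lung Cancer	Lung	NSCLC
Thyroid Cancer	Thyroid	THCA;Thyroid Carcinoma
Medullary Thyroid Cancer	Thyroid	MTC
Melanoma	Skin	Cutaneous Melanoma;SKCM
Colorectal Adenocarcinoma	Bowel	CRC;Colorectal Cancer
Glioblastoma	CNS/Brain	GBM;Glioblastoma Multiforme
Breast Invasive Ductal Carcinoma	Breast	IDC
Pancreatic Adenocarcinoma	Pancreas	PAAD
All Solid Tumors	Other	Solid Tumor;Any solid tumor
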