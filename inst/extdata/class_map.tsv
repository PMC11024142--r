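source_label	cupid_class	exclude	reason
Adrenocortical carcinoma	ACC	FALSE	.
Bladder urothelial carcinoma	BLCA	FALSE	.
Breast invasive carcinoma	BRCA	FALSE	.
Cervical squamous cell carcinoma	CervSq	FALSE	.
Cervical adenosquamous	NA	TRUE	mixed histology
Cholangiocarcinoma	CHOL	FALSE	.
Diffuse large B-cell lymphoma	DLBC	FALSE	.
Glioblastoma multiforme	GBM	FALSE	.
Endocervical adenocarcinoma	Gynae	FALSE	.
Ovarian cystadenocarcinoma	Gynae	FALSE	.
Endometrial carcinoma	Gynae	FALSE	.
Uterine carcinosarcoma	Gynae	FALSE	.
Kidney chromophobe	KICH	FALSE	.
Kidney renal clear cell carcinoma	KIRC	FALSE	.
Kidney renal papillary cell carcinoma	KIRP	FALSE	.
Acute myeloid leukaemia	LAML	FALSE	.
Brain lower grade glioma	LGG	FALSE	.
Liver hepatocellular carcinoma	LIHC	FALSE	.
Hepatocholangiocarcinoma (Mixed)	NA	TRUE	mixed histology
Colon adenocarcinoma	LowerGI	FALSE	.
Rectum adenocarcinoma	LowerGI	FALSE	.
Lung adenocarcinoma	LUAD	FALSE	.
Lung squamous cell carcinoma	LUSC	FALSE	.
Mesothelioma	MESO	FALSE	.
Pancreatic adenocarcinoma	PAAD	FALSE	.
Pheochromocytoma and Paraganglioma	PCPG	FALSE	.
Prostate adenocarcinoma	PRAD	FALSE	.
Sarcoma	SARC	FALSE	.
Skin cutaneous melanoma	SKCM	FALSE	.
Testicular germ cell tumours	TGCT	FALSE	.
Thyroid carcinoma	THCA	FALSE	.
Thymoma	THYM	FALSE	.
Oesophagus adenocarcinoma	UpperGI	FALSE	.
Stomach adenocarcinoma	UpperGI	FALSE	.
Oesophagus squamous cell carcinoma	UpperSq	FALSE	.
Head and neck squamous cell carcinoma	UpperSq	FALSE	.
Uveal melanoma	UVM	FALSE	.
Adjacent normal liver	NCC	FALSE	.
Non-cancer control	NCC	FALSE	.
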