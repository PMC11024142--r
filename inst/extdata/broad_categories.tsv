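cupid_class	category
CHOL	HepatoPancreatoBiliary
LIHC	HepatoPancreatoBiliary
PAAD	HepatoPancreatoBiliary
Gynae	FemaleGenitalTract
CervSq	FemaleGenitalTract
UpperGI	Gastrointestinal
LowerGI	Gastrointestinal
UpperSq	Gastrointestinal
LUAD	Lung
LUSC	Lung
BLCA	Urological
PRAD	Urological
KICH	Urological
KIRC	Urological
KIRP	Urological
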