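pattern	category
extracellular matrix|collagen|ECM|structural|proteoglycan|basement membrane	ECM and structural tissue constituent
differentiation|development|cell fate|morphogenesis|chondro|osteo|ossification|cartilage	cell fate, differentiation and development
cytoskelet|actin|microtubule|filament	cytoskeleton
hypoxia|oxidative|inflammat|mechanical|stress|microenvironment|wound	microenvironmental response
signaling|signal transduction|pathway|kinase|SMAD|TGF|BMP|FGF|IGF|Hippo|Wnt|integrin	signaling networks
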