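# topolabel modification table: residual modifications left on lysines (and
# cysteines) by cleavable sulfo-NHS-SS-biotin surface labeling and downstream
# reductive/alkylative processing. Masses are monoisotopic, recomputed from the
# composition column at load time; the mass column is informative only.
name	target	composition	mass	note
thioacyl	K	C3H4OS	87.998	residual stub after disulfide reduction
thioacyl-biotin	K	C15H23N3O3S3	389.090	intact label (formic-acid elution)
carbamidomethylthio-propanoyl	K	C5H7NO2S	145.020	thioacyl + carbamidomethyl (iodoacetamide)
thioacyl-aminoethyl	K	C5H9NOS	131.040	Thio(AE): thioacyl + aminoethyl
thioacyl-NEM	K	C9H11NO3S	213.046	Thio(NEM); commonly quoted rounded as 213.045
aminoethyl	C	C2H5N	43.04	cysteine alkylation
N-ethylmaleimide	C	C6H7NO2	125.048	cysteine alkylation
carbamidomethyl	C	C2H3NO	57.021	cysteine alkylation (iodoacetamide)
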