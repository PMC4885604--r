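surface	class
induce	POSITIVE_REG
activate	POSITIVE_REG
promote	POSITIVE_REG
enhance	POSITIVE_REG
upregulate	POSITIVE_REG
stimulate	POSITIVE_REG
accelerate	POSITIVE_REG
facilitate	POSITIVE_REG
increase	POSITIVE_REG
inhibit	NEGATIVE_REG
suppress	NEGATIVE_REG
repress	NEGATIVE_REG
downregulate	NEGATIVE_REG
attenuate	NEGATIVE_REG
block	NEGATIVE_REG
abolish	NEGATIVE_REG
impair	NEGATIVE_REG
reduce	NEGATIVE_REG
decrease	NEGATIVE_REG
regulate	NEUTRAL_REG
modulate	NEUTRAL_REG
mediate	NEUTRAL_REG
control	NEUTRAL_REG
affect	NEUTRAL_REG
influence	NEUTRAL_REG
metastasize	METASTASIS_TRIGGER
spread	METASTASIS_TRIGGER
disseminate	METASTASIS_TRIGGER
colonize	METASTASIS_TRIGGER
invade	METASTASIS_TRIGGER
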