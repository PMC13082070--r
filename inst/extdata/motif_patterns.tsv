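# Short-linear-motif patterns (editable). Approximate defaults standing in
# for the full ELM Resource lists: classic NLS regexes, a subset of MOD-class
# PTM site patterns, and RNA-interaction elements.
name	class	regex
NLS_monopartite_classic	NLS	K[KR].[KR]
NLS_monopartite_4R	NLS	[KR]{4}
NLS_bipartite	NLS	[KR]{2}.{9,12}[KR]{3}
MOD_CK2_1	MOD	([ST])..[DE]
MOD_PKA_1	MOD	[RK][RK].([ST])
MOD_CDK_SPK_2	MOD	([ST])P[RK]
MOD_PIKK_1	MOD	([ST])Q
MOD_GSK3_1	MOD	([ST]).{3}[ST]
MOD_NMyristoyl	MOD	^G[^EDRKHPFYW]..[STAGCN]
RGG	RNA	RGG
RG	RNA	RG[^G]
FYGG	RNA	[FY]GG
SYG	RNA	SYG
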