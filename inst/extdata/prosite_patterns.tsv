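# Bundled PROSITE-syntax patterns: the triosephosphate isomerase
# active-site pattern and classical kinase phosphorylation-site patterns.
PS00171	[AVG]-[YF]-E-P-[LIVM]-W-[SAC]-[IV]-G-[TK]-G.
PS00004	[RK](2)-x-[ST].
PS00005	[ST]-x-[RK].
PS00006	[ST]-x(2)-[DE].
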