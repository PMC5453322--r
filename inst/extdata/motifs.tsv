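# default localization-motif patterns: term_id <TAB> regex
# monopartite nuclear localization signal
EX:0501	K[KR].[KR]
# bipartite nuclear localization signal
EX:0502	[KR][KR].{10,12}[KR]{3}
# CRM1-type nuclear export signal
EX:0503	L.{2,3}[LIVFM].{2,3}L.[LI]
# C-terminal peroxisomal targeting signal 1
EX:0504	[SAC][KRH][LM]$
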