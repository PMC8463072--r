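# Mouse core and linker histone gene symbols (old Hist* and current
# nomenclature), matched case-insensitively against MaxQuant "Gene names".
Hist1h1a
Hist1h1b
Hist1h1c
Hist1h1d
Hist1h1e
Hist1h1t
H1f0
H1f1
H1f2
H1f3
H1f4
H1f5
H1f10
H1fx
Hist1h2aa
Hist1h2ab
Hist1h2ac
Hist1h2ad
Hist1h2ae
Hist2h2aa1
Hist2h2ac
Hist3h2a
H2afx
H2afy
H2afz
H2ac1
H2ac4
H2ac8
H2ac20
H2ax
H2az1
H2az2
Macroh2a1
Hist1h2ba
Hist1h2bb
Hist1h2bc
Hist1h2be
Hist1h2bf
Hist1h2bj
Hist1h2bk
Hist1h2bl
Hist2h2bb
Hist2h2be
Hist3h2ba
H2bc1
H2bc3
H2bc4
H2bc21
Hist1h3a
Hist1h3b
Hist1h3c
Hist2h3b
Hist3h3
H3f3a
H3f3b
H3c1
H3c2
H3c8
H3-3a
H3-3b
Cenpa
Hist1h4a
Hist1h4b
Hist1h4c
Hist1h4d
Hist2h4
H4c1
H4c2
H4c3
H4c4
H4c11
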