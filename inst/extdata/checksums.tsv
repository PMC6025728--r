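file	md5
table1.tsv	3537c671e8572aff7dfc0c2a8d245044
table2.tsv	da914e798ed8d75e8750195054df2f1f
table3.tsv	d18a733f9b6a3b5897f8450bb08215b0
dependency_matrix.tsv	d847380ea0b553ce0f7e5f1e7927798f
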