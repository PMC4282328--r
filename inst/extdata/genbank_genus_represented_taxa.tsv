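order	families	genera
Archaeognatha	2	9
Blattodea	12	72
Coleoptera	118	1956
Dermaptera	4	5
Diptera	79	739
Embioptera	6	9
Ephemeroptera	21	76
Grylloblattodea	1	1
Hemiptera	83	892
Hymenoptera	53	728
Lepidoptera	110	3362
Mantodea	8	56
Mantophasmatodea	2	5
Mecoptera	5	7
Megaloptera	2	5
Neuroptera	16	69
Odonata	13	57
Orthoptera	19	243
Phasmatodea	9	63
Phthiraptera	7	10
Plecoptera	11	46
Psocoptera	2	2
Raphidioptera	2	4
Siphonaptera	3	6
Strepsiptera	4	6
Thysanoptera	3	44
Trichoptera	35	203
Zygentoma	3	4
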