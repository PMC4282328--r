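order	families	genera
Archaeognatha	2	64
Blattodea	17	738
Coleoptera	176	29500
Dermaptera	11	182
Diptera	158	9323
Embioptera	11	84
Ephemeroptera	42	405
Grylloblattodea	1	5
Hemiptera	108	
Hymenoptera	89	8359
Lepidoptera	131	15528
Mantodea	14	436
Mantophasmatodea	2	10
Mecoptera	9	32
Megaloptera	2	33
Neuroptera	16	
Odonata	31	642
Orthoptera	40	4418
Phasmatodea	13	454
Phthiraptera	15	50
Plecoptera	16	286
Psocoptera	40	320
Raphidioptera	2	18
Siphonaptera	16	246
Strepsiptera	8	
Thysanoptera	9	767
Trichoptera	49	601
Zygentoma	3	117
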