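glycosaminoglycan_binding	GO term enriched among downregulated genes (GSE58915 study)	Smoc2	Fgfr1	App	Ccdc80	Tgfbr3	Fstl1	Adamts1	Tpsb2	Thbs1	Pcolce2	Fn1	Cyr61
polysaccharide_binding	glycosaminoglycan binding genes plus Enpp2 and Agl	Smoc2	Fgfr1	App	Ccdc80	Tgfbr3	Fstl1	Adamts1	Tpsb2	Thbs1	Pcolce2	Fn1	Cyr61	Enpp2	Agl
morphogenesis_of_an_epithelium	GO term enriched among downregulated genes (GSE58915 study)	Fgfr3	Nrp1	Lmo4	Npnt	Smad4	Igf1	Jag1	Pthlh	Igf1r	Sfrp1	Sema3c	Tgif1	Chuk
proteinaceous_extracellular_matrix	GO term enriched among downregulated genes (GSE58915 study)	Matn2	Col4a2	Lum	Npnt	Adamts15	Ccdc80	Sparc	Timp3	Prelp	Smoc2	Gpc6	TgfbI	Tgfbr3	Adamts1	Mfap4	Col11a1	Fn1
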