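locus	chrom	pos
chr5:33Mb	chr5	33855429
chr5:33Mb	chr5	33993463
chr5:33Mb	chr5	34005879
chr5:33Mb	chr5	34012145
chr5:33Mb	chr5	34028329
chr5:33Mb	chr5	34043717
chr5:33Mb	chr5	34076942
chr5:33Mb	chr5	34083675
chr5:33Mb	chr5	34087262
chr5:33Mb	chr5	34087720
chr5:33Mb	chr5	34100829
chr5:33Mb	chr5	34103314
chr5:33Mb	chr5	34109473
chr5:33Mb	chr5	34120114
chr5:33Mb	chr5	34421555
chr5:33Mb	chr5	34425934
chr5:33Mb	chr5	34428714
chr5:33Mb	chr5	34433959
chr5:33Mb	chr5	34434313
chr5:33Mb	chr5	34436053
chr5:33Mb	chr5	34440306
chr5:33Mb	chr5	34440578
chr5:33Mb	chr5	34442862
chr5:33Mb	chr5	34448188
chr5:33Mb	chr5	34449394
chr5:33Mb	chr5	34455245
chr5:33Mb	chr5	34529929
chr11:41Mb	chr11	41258181
chr11:41Mb	chr11	41275129
chr11:41Mb	chr11	41275213
chr11:41Mb	chr11	41277330
chr11:41Mb	chr11	41280608
chr11:41Mb	chr11	41290542
chr11:41Mb	chr11	41298930
chr11:41Mb	chr11	41306401
chr11:41Mb	chr11	41310312
chr11:41Mb	chr11	41313739
chr11:41Mb	chr11	41317800
chr11:41Mb	chr11	41329384
chr11:41Mb	chr11	41330760
chr11:41Mb	chr11	41332109
chr11:41Mb	chr11	41366494
chr11:44Mb	chr11	43510563
chr11:44Mb	chr11	43519952
chr11:44Mb	chr11	43537944
chr11:44Mb	chr11	43565114
chr11:44Mb	chr11	43939450
chr11:44Mb	chr11	44316022
chr11:44Mb	chr11	44342776
chr11:44Mb	chr11	44343823
chr11:44Mb	chr11	44344884
chr11:44Mb	chr11	44366118
chr11:44Mb	chr11	44371942
chr11:44Mb	chr11	44374045
chr11:44Mb	chr11	44380626
chr11:44Mb	chr11	44395661
chr11:44Mb	chr11	44397515
chr11:44Mb	chr11	44609562
chr11:44Mb	chr11	44611627
chr11:44Mb	chr11	44612055
chr14:11Mb	chr14	10887016
chr14:11Mb	chr14	10889217
chr14:11Mb	chr14	10891570
chr14:11Mb	chr14	10893694
chr14:11Mb	chr14	10895560
chr14:11Mb	chr14	10898604
chr14:11Mb	chr14	10906919
chr14:11Mb	chr14	10932956
chr14:11Mb	chr14	10936449
chr14:11Mb	chr14	10943176
chr14:11Mb	chr14	10949045
chr14:11Mb	chr14	10958187
chr14:11Mb	chr14	10960590
chr14:11Mb	chr14	10974467
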