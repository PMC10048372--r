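label	trait	omia_id	gene	chrom	pos	ref	alt	descriptor	n_refref	n_refalt	n_altalt	freq_published
SOD1_c118	Degenerative myelopathy	000263-9615	SOD1	chr31	27123057	G	A	chr31:g.27123057G>A	10	21	2	0.379
SOD1_c52	Degenerative myelopathy	000263-9615	SOD1	chr31	27118886	A	T	chr31:g.27118886A>T	32	1	0	0.015
SP110_42620442	Degenerative myelopathy	000263-9615	SP110	chr25	42620442	G	A	chr25:g.42620442G>A	4	15	14	0.652
SP110_42623004	Degenerative myelopathy	000263-9615	SP110	chr25	42623004	C	T	chr25:g.42623004C>T	5	14	14	0.636
SP110_42628769	Degenerative myelopathy	000263-9615	SP110	chr25	42628769	C	T	chr25:g.42628769C>T	23	9	1	0.167
SP110_42631341	Degenerative myelopathy	000263-9615	SP110	chr25	42631341	G	A	chr25:g.42631341G>A	23	9	1	0.167
SP110_42633078	Degenerative myelopathy	000263-9615	SP110	chr25	42633078	T	A	chr25:g.42633078T>A	14	15	4	0.348
GFAP_18459694	Alexander disease	001208-9615	GFAP	chr9	18459694	G	A	chr9:g.18459694G>A	33	0	0	0.000
IGF1_41511739	Height	002524-9615	IGF1	chr15	41511739	T	C	chr15:g.41511739T>C	31	2	0	0.030
MSRB3_8395407	Ear type	000319-9615	MSRB3	chr10	8395407	GTTTATTTTAT	G	chr10:g.8395407delTTTATTTTAT	1	0	32	0.970
FGF5_35475211	Hair length	000439-9615	FGF5	chr32	35475211	G	A	chr32:g.35475211G>A	33	0	0	0.000
FGF5_35475230dup	Hair length	000439-9615	FGF5	chr32	35475230	C	CCA	chr32:g.35475230_35475231dup	33	0	0	0.000
FGF5_35475218del	Hair length	000439-9615	FGF5	chr32	35475218	N	<DEL>	chr32:g.35475218_35475233del	33	0	0	0.000
FGF5_35486609	Hair length	000439-9615	FGF5	chr32	35486609	A	T	chr32:g.35486609A>T	33	0	0	0.000
FGF5_35494497	Hair length	000439-9615	FGF5	chr32	35494497	C	A	chr32:g.35494497C>A	0	0	33	1.000
ASIP_complex	Coat color	000601-9615	ASIP	chr24	23863804	N	<COMPLEX>	chr24:g.[23863804_23863988del;23865233_23865267A;23891659_23891781delins]	0	0	33	1.000
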