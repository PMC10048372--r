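##gff-version 3
##sequence-region 2 1 90000000
2	synthetic	gene	71840000	71852000	.	+	.	ID=gene1;Name=SMPDL3B
2	synthetic	gene	71855000	71868000	.	-	.	ID=gene2;Name=RPA2
2	synthetic	gene	71870000	71901000	.	+	.	ID=gene3;Name=THEMIS2
2	synthetic	gene	71903000	71912000	.	+	.	ID=gene4;Name=LOC119870383
2	synthetic	gene	71915000	71930000	.	-	.	ID=gene5;Name=PPP1R8
2	synthetic	gene	71933000	71945500	.	+	.	ID=gene6;Name=LOC119870569
2	synthetic	gene	72100000	72150000	.	+	.	ID=gene7;Name=OUTSIDE1
2	synthetic	gene	71000000	71500000	.	-	.	ID=gene8;Name=UPSTREAM1
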