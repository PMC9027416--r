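assembly	contigs	length_bp	coverage	p_dist	errors
Flye +1p	circular	16690	20	0.001023172	65
Flye +1p + Medaka	circular	16475	20	0.000541679	70
Flye +5p	circular	16691	20	0.001023172	69
Flye +5p + Medaka	circular	16475	20	0.000541679	71
Flye +10p	circular	16691	20	0.001023172	69
Flye +10p + Medaka	circular	16475	20	0.000541679	71
Unicycler - N	circular	16801	2.28	0.001143545	110
Unicycler - N + Medaka	circular	16781	2.28	0.000601866	89
Unicycler - B	circular	16801	2.28	0.001143545	110
Unicycler - B + Medaka	circular	16781	2.28	0.000601866	89
Unicycler - C	circular	16801	2.28	0.001143545	110
Unicycler - C + Medaka	circular	16781	2.28	0.000601866	89
Rebaler - P. amblyrhynchos	circular	15782	50.59	0.001324105	106
Rebaler - P. ambly. + Medaka	circular	16774	50.59	0.000541679	81
Rebaler - P. amboinensis	circular	15790	49.94	0.000902799	95
Rebaler - P. ambo. + Medaka	circular	16776	49.94	0.000361119	73
Rebaler - P. falciformis	circular	16789	52.52	0.000842612	96
Rebaler - P. falci. + Medaka	circular	16777	52.52	0.000541679	81
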