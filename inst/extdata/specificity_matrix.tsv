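event	crop	status	P-35S	P-FMV	P-nos	P-Rice actin	P-SSuAra	T-35S	T-E9	T-g7	T-nos	CP4-epsps	Cry1A(b)	Cry1A.105	Cry1Ab/Ac	Cry1F	Cry2Ab2	Cry3Bb1	Vip3A	bar	pat	nptII	I-rAct1	Barstar	CaMV	ctp2/CP4-epsps	ctp4/CP4-epsps
A2704-12 soy	soy	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
A5547-127 soy	soy	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
CV127 soy	soy	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
DAS44406 soy	soy	unknown	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
DAS68416 soy	soy	unknown	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
DAS81419 soy	soy	unknown	-	-	-	-	-	-	-	-	-	-	-	-	+	X	-	-	-	-	+	-	-	-	-	-	-
DP305423 soy	soy	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
DP356043 soy	soy	unknown	X	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
FG72 soy	soy	unknown	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
GTS 40-3-2 soy	soy	unknown	+	-	-	-	-	-	-	-	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+
MON87701 soy	soy	unknown	-	-	-	-	+	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-
MON87705 soy	soy	unknown	-	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
MON87708 soy	soy	unknown	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MON87769 soy	soy	unknown	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MON89788 soy	soy	unknown	-	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
3272 maize	maize	unknown	-	-	-	-	-	X	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
5307 maize	maize	unknown	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	X	-	-	-	-	-	-	-	-	-
Bt11 maize	maize	unknown	+	-	-	-	-	+*	-	-	+	-	+	-	X	-	-	-	-	-	+	-	-	-	-	-	-
Bt176 maize	maize	unknown	+	-	-	-	-	X	-	-	-	-	+	-	X	-	-	-	-	+	-	-	-	-	-	-	-
CBH351 maize	maize	unknown	+	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	+	-	+	-	-	-	-	-
DAS40278 maize	maize	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
DAS59122 maize	maize	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
DAS59132 (E32) maize	maize	unauthorised	+	-	-	-	-	-	-	-	-	-	-	-	-	(+)	-	-	-	-	+	-	-	-	-	-	-
DP98140 maize	maize	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
GA21 maize	maize	unknown	-	-	-	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-
MIR162 maize	maize	unknown	-	-	-	-	-	X	-	-	+	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-
MIR604 maize	maize	unknown	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	X	-	-	-	-	-	-	-	-	-
MON810 maize	maize	unknown	+	-	-	-	-	-	-	-	-	-	+	X	-	-	-	-	-	-	-	-	-	-	-	-	-
MON863 maize	maize	unknown	+	-	-	-	-	-	-	-	+	-	-	-	-	-	-	+	-	-	-	+	+	-	-	-	-
MON87427 maize	maize	unknown	+	-	-	-	-	-	-	-	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
MON87460 maize	maize	unknown	+	-	-	X	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	+	+	-	-	-	-
MON88017 maize	maize	unknown	+	-	-	+	-	-	-	-	+	+	-	-	-	-	-	+	-	-	-	-	+	-	-	+	-
MON89034 maize	maize	unknown	+	+	-	-	-	-	-	-	+	-	+	+	-	-	+	-	-	-	-	-	+	-	-	-	-
NK603 maize	maize	unknown	+	-	-	+	-	-	-	-	+	+	-	-	-	-	-	-	-	-	-	+	+	-	-	+	-
T25 maize	maize	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
TC1507 maize	maize	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	+	-	-	-	-	+	-	-	-	-	-	-
DP73496 canola	canola	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MON88302 canola	canola	unknown	-	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
Ms1 canola	canola	unknown	-	-	+	-	+	-	-	+	+	-	-	-	-	-	-	-	-	+	-	+	-	-	-	-	-
Ms8 canola	canola	unknown	-	-	-	-	+	-	-	+	+	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-
Rf1 canola	canola	unknown	-	-	+	-	+	-	-	+	+	-	-	-	-	-	-	-	-	+	-	+	-	+	-	-	-
Rf2 canola	canola	unknown	-	-	+	-	+	-	-	+	+	-	-	-	-	-	-	-	-	+	-	+	-	+	-	-	-
Rf3 canola	canola	unknown	-	-	-	-	+	-	-	+	+	-	-	-	-	-	-	-	-	+	-	-	-	+	-	-	-
GT73 canola	canola	unknown	-	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
T45 canola	canola	unknown	+	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-
TOPAS 19/2 canola	canola	unknown	+	-	+	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	+	+	-	-	-	-	-
EH92-527-1 potato	potato	unknown	-	-	+	-	-	-	-	-	+	-	-	-	-	-	-	-	-	-	-	+	-	-	-	-	-
281-24-236x3006-210-23 cotton	cotton	unknown	-	-	-	-	-	-	-	-	-	-	-	-	X	+	-	-	-	-	+	-	-	-	-	-	-
GHB119 cotton	cotton	unknown	+	-	-	-	-	+	-	-	+	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-
GHB614 cotton	cotton	unknown	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
LL25 cotton	cotton	unknown	+	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-	-	+	-	-	-	-	-	-	-
MON1445 cotton	cotton	unknown	+	+	-	-	-	-	+	-	+	X	-	-	-	-	-	-	-	-	-	+	-	-	-	+	-
MON15985 cotton	cotton	unknown	+	-	-	-	-	-	-	-	+	-	+	-	+	-	+	-	-	-	-	+	-	-	-	-	-
MON531 cotton	cotton	unknown	+	-	-	-	-	-	-	-	+	-	+	-	+	-	-	-	-	-	-	+	-	-	-	-	-
MON88913 cotton	cotton	unknown	+	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
T304-40 cotton	cotton	unknown	+	-	-	-	-	-	-	-	+	-	+	-	-	-	-	-	-	+	-	-	-	-	-	-	-
Bt63 rice construct	rice	unauthorised				(+)					+		+		+								(+)				
LL601 rice	rice	unauthorised	+	-	-	(+)	-	+	-	-	-	-	-	-	-	-	-	-	-	+	-	-	(+)	-	-	-	-
LL62 rice	rice	unknown	+	-	-	+	-	+	-	-	-	-	-	-	-	-	-	-	-	+	-	-	+	-	-	-	-
H7-1 sugar beet	sugar beet	unknown	-	+	-	-	-	-	+	-	-	X	-	-	-	-	-	-	-	-	-	-	-	-	-	+	-
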