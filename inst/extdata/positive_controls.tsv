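assay	control_material	material_crop
Plant actin	A2704-12 soy	soy
Canola FatA	non-modified canola AOCS0306B	canola
Maize HMG	MIR162 maize	maize
Rice SPS	non-modified rice AOCS0306D	rice
Soy Lec	DP305423 soy	soy
Sugar beet GS	H7-1 sugar beet	sugar beet
Wheat Wx-1	common wheat	wheat
P-35S	MON810 maize	maize
P-FMV	MON89788 soy	soy
P-nos	Rf1 canola	canola
P-Rice actin	NK603 maize	maize
P-SSuAra	MON87701 soy	soy
T-35S	TC1507 maize	maize
T-E9	MON89788 soy	soy
T-g7	Rf1 canola	canola
T-nos	NK603 maize	maize
CP4-epsps	MON810 maize	maize
Cry1A(b)	MON810 maize	maize
Cry1A.105	MON89034 maize	maize
Cry1Ab/Ac	MON87701 soy	soy
Cry1F	TC1507 maize	maize
Cry2Ab2	MON89034 maize	maize
Cry3Bb1	MON863 maize	maize
Vip3A	MIR162 maize	maize
bar	Rf1 canola	canola
pat	TC1507 maize	maize
nptII	MON863 maize	maize
I-rAct1	MON863 maize	maize
Barstar	Rf1 canola	canola
CaMV	CaMV positive sample
ctp2/CP4-epsps	NK603 maize	maize
ctp4/CP4-epsps	MON810 maize	maize
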