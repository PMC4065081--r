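superfamily	signal_peptide	propeptide_anchor	framework	families	has_propeptide
I	MKASMFLAFAGLVLLFVVCYA		I	HWTX-I,HWTX-III,HWTX-IV,HWTX-V,SHL	TRUE
II	MKVTLIAILTCAAVLVLHTTAA		II	HWTX-II,HWTX-VII	TRUE
X	MNMKILVLVAVLCLVVSTHA		I	HWTX-X	TRUE
XI	MGIARILSAVLFLSVLFVVTFPALLSAD		II	HWTX-XI	FALSE
XIII	MKYAIVLCVIVIVVTVVRA		I	HWTX-XIII	TRUE
XIV	MKVVLLVCLVWMMAMMELVSC		VI	HWTX-XIV	FALSE
XV	MKHFASCIFSVLTVAICGVSQT		III	HWTX-XV,HWTX-XXVIII	TRUE
XVI	MNTVRVTFLLVFVLAVSLGQA		I	HWTX-XVI	TRUE
XVII	MKIATFLGLSFLLIASYVLICEA		III	HWTX-XVII	TRUE
XVIII	MKLSLIIIATSLVIAVVA		IV	HWTX-XVIII	TRUE
XX	MKLSNFAVVLVGILFVSVPLFA		VII	HWTX-XX,HWTX-XIX	TRUE
XXI	MLATFIVLFVPIFRNPLCCFQCQVYG		X	HWTX-XXI	TRUE
XXII	MTWLLMVPLMLLSPLLQIAC		IX	HWTX-XXII	TRUE
XXIII	MIVLGGMAFSVTSMVVACVV		VIII	HWTX-XXIII	FALSE
XXIV	MVCATRRLIRLLSSSG		II	HWTX-XXIV	FALSE
XXV		MTREETQSLGEHEKDEEVTGSEER	XI	HWTX-XXV,HWTX-XXVI	TRUE
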