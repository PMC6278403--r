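# Curated fixture set of short bioactive peptides (synthetic stand-in for a
# public bioactive-peptide database snapshot; counts against it are fixture-
# relative only). Sources are indicative literature anchors, not a registry.
sequence	activity	ref_id	source
GP	DPP-IV inhibitor	PSF0001	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012 (dairy-derived DPP-IV inhibitors)
AP	DPP-IV inhibitor	PSF0002	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
VP	DPP-IV inhibitor	PSF0003	Xaa-Pro dipeptide; Nongonierma & FitzGerald 2014
IP	DPP-IV inhibitor	PSF0004	Xaa-Pro dipeptide; Nongonierma & FitzGerald 2014
LP	DPP-IV inhibitor	PSF0005	Xaa-Pro dipeptide; Nongonierma & FitzGerald 2014
FP	DPP-IV inhibitor	PSF0006	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
MP	DPP-IV inhibitor	PSF0007	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
WP	DPP-IV inhibitor	PSF0008	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
HP	DPP-IV inhibitor	PSF0009	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
SP	DPP-IV inhibitor	PSF0010	Xaa-Pro dipeptide; Ser at P2 motif, Davy et al. 2000
KP	DPP-IV inhibitor	PSF0011	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
RP	DPP-IV inhibitor	PSF0012	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
TP	DPP-IV inhibitor	PSF0013	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
YP	DPP-IV inhibitor	PSF0014	Xaa-Pro dipeptide; Lacroix & Li-Chan 2012
GA	DPP-IV inhibitor	PSF0015	Xaa-Ala dipeptide; Ala at P2 motif, Davy et al. 2000
VA	DPP-IV inhibitor	PSF0016	Xaa-Ala dipeptide; Nongonierma & FitzGerald 2014
WV	DPP-IV inhibitor	PSF0017	Trp-Val; Nongonierma & FitzGerald 2013
KF	DPP-IV inhibitor	PSF0018	Lys-Phe; multi-activity dipeptide
IPI	DPP-IV inhibitor	PSF0019	diprotin A; Umezawa et al. 1984
VPL	DPP-IV inhibitor	PSF0020	diprotin B; Umezawa et al. 1984
IPA	DPP-IV inhibitor	PSF0021	beta-lactoglobulin tryptic fragment; Tulipano et al. 2011
LPL	DPP-IV inhibitor	PSF0022	milk-protein-derived; Nongonierma & FitzGerald 2013
VY	ACE inhibitor	PSF0101	sardine-muscle dipeptide; Matsufuji et al. 1994
IY	ACE inhibitor	PSF0102	wakame-derived; Suetsuna & Nakano 2000
AY	ACE inhibitor	PSF0103	wakame-derived; Suetsuna & Nakano 2000
GY	ACE inhibitor	PSF0104	rice-protein-derived dipeptide
RY	ACE inhibitor	PSF0105	sake-lees-derived; Saito et al. 1994
VW	ACE inhibitor	PSF0106	sake-lees-derived; Saito et al. 1994
IW	ACE inhibitor	PSF0107	whey-derived; Martin et al. 2008
LW	ACE inhibitor	PSF0108	alpha-lactalbumin fragment
AW	ACE inhibitor	PSF0109	fish-muscle-derived dipeptide
FY	ACE inhibitor	PSF0110	sardine-muscle dipeptide; Matsufuji et al. 1994
AF	ACE inhibitor	PSF0111	sardine-muscle dipeptide; Matsufuji et al. 1994
VF	ACE inhibitor	PSF0112	sardine-muscle dipeptide; Matsufuji et al. 1994
KW	ACE inhibitor	PSF0113	sardine-muscle dipeptide; Matsufuji et al. 1994
RF	ACE inhibitor	PSF0114	fish-protein-derived dipeptide
GF	ACE inhibitor	PSF0115	casein-derived dipeptide
YL	ACE inhibitor	PSF0116	casein-derived dipeptide; Maruyama & Suzuki 1982
IPP	ACE inhibitor	PSF0117	Ile-Pro-Pro, sour-milk lactotripeptide; Nakamura et al. 1995
VPP	ACE inhibitor	PSF0118	Val-Pro-Pro, sour-milk lactotripeptide; Nakamura et al. 1995
IKW	ACE inhibitor	PSF0119	chicken-muscle tripeptide; Fujita et al. 2000
LKP	ACE inhibitor	PSF0120	chicken-muscle tripeptide; Fujita et al. 2000
LRP	ACE inhibitor	PSF0121	maize alpha-zein tripeptide; Miyoshi et al. 1991
IPP	antihypertensive	PSF0201	lactotripeptide with in vivo blood-pressure effect
VPP	antihypertensive	PSF0202	lactotripeptide with in vivo blood-pressure effect
KF	antihypertensive	PSF0203	multi-activity dipeptide
KF	hypotensive	PSF0204	multi-activity dipeptide
KF	other:inhibitor	PSF0205	multi-activity dipeptide
AY	antioxidative	PSF0301	radical-scavenging dipeptide
WY	antioxidative	PSF0302	radical-scavenging dipeptide; Saito et al. 2003
YL	antioxidative	PSF0303	radical-scavenging dipeptide
LH	antioxidative	PSF0304	His-containing dipeptide; Chen et al. 1996
HL	antioxidative	PSF0305	His-containing dipeptide; Chen et al. 1996
MY	antioxidative	PSF0306	Met-Tyr; Erdmann et al. 2008
EL	antioxidative	PSF0307	Glu-Leu; Suetsuna et al. 2000
PW	antioxidative	PSF0308	Pro-Trp; Saito et al. 2003
HH	antioxidative	PSF0309	His-His; Chen et al. 1998
GPP	antioxidative	PSF0310	collagen-like Gly-Pro-Pro fragment
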