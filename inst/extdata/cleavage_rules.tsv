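# Protease cleavage-specificity rulebook.
#
# Grammar: one row per clause. `kind` is "site" (proposes a cut) or
# "exception" (vetoes a proposed cut). Columns p2, p1, p1p, p2p give the
# allowed residue set (a string of one-letter codes) at window positions
# P2, P1, P1', P2' around the scissile bond, which lies between P1 and P1'.
# "." means unconstrained. A bond is cut iff at least one site clause
# matches its window and no exception clause does. Window positions beyond
# the sequence termini satisfy unconstrained positions and fail constrained
# ones.
#
# Encodings follow the public PeptideCutter-style specificity conventions,
# simplified to the P2..P2' window; specificity variants exist between
# tools, so absolute released-peptide counts depend on this encoding (and
# on the reference peptide table) and are not comparable across tools.
enzyme	ec	kind	p2	p1	p1p	p2p
trypsin	3.4.21.4	site	.	KR	.	.
trypsin	3.4.21.4	exception	.	.	P	.
chymotrypsin_A	3.4.21.1	site	.	FYW	.	.
chymotrypsin_A	3.4.21.1	exception	.	.	P	.
chymotrypsin_A	3.4.21.1	exception	.	W	M	.
chymotrypsin_C	3.4.21.2	site	.	FLYWMH	.	.
chymotrypsin_C	3.4.21.2	exception	.	.	P	.
chymotrypsin_C	3.4.21.2	exception	.	W	M	.
chymotrypsin_C	3.4.21.2	exception	.	M	Y	.
chymotrypsin_C	3.4.21.2	exception	.	H	DMW	.
pepsin_ph2	3.4.23.1	site	.	FLWY	.	.
pepsin_ph2	3.4.23.1	site	.	.	FLWY	.
pepsin_ph2	3.4.23.1	exception	P	.	.	.
pepsin_ph2	3.4.23.1	exception	.	P	.	.
pepsin_ph2	3.4.23.1	exception	.	.	P	.
pepsin_ph2	3.4.23.1	exception	.	HKR	.	.
papain	3.4.22.2	site	AFILMVWY	KR	.	.
papain	3.4.22.2	exception	.	.	P	.
bromelain	3.4.22.32	site	.	KRFY	.	.
bromelain	3.4.22.32	exception	.	.	P	.
ficin	3.4.22.3	site	.	FY	.	.
ficin	3.4.22.3	exception	.	.	P	.
thermolysin	3.4.24.27	site	.	.	AFILMV	.
thermolysin	3.4.24.27	exception	.	DE	.	.
thermolysin	3.4.24.27	exception	.	.	.	P
proteinase_K	3.4.21.67	site	.	AEFILTVWY	.	.
pancreatic_elastase	3.4.21.36	site	.	AGSV	.	.
pancreatic_elastase	3.4.21.36	exception	.	.	P	.
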