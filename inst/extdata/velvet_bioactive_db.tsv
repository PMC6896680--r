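sequence	name	activity	source
LVVYPWTQR	LVV-hemorphin-6	opioid	velvet-study:matched
LVVYPWTQR	LVV-hemorphin-6	ACE inhibitor	velvet-study:matched
FLSFPTTKTYFPHFDLSHGSAQVKGHGAK	Bovine haemoglobin peptide	antimicrobial	velvet-study:matched
TRSSRAGLQFPVGRVHRLLRK	Buforin II	antimicrobial	velvet-study:matched
QVSLNSGYY	ACE inhibitor peptide	ACE inhibitor	velvet-study:matched
VLSAADKSNVKAAWGKVGGNAPAFGAEALLRM	Wound healing peptide	wound healing/immunomodulatory	velvet-study:matched
LVVYPW	Myelopeptide MP-2	wound healing/immunomodulatory	velvet-study:free
LVVYPWTQ	LVV-hemorphin-5	opioid	velvet-study:free
LVVYPWTQ	LVV-hemorphin-5	ACE inhibitor	velvet-study:free
VVYPWTQ	VV-hemorphin-5	opioid	velvet-study:free
VVYPWTQ	VV-hemorphin-5	ACE inhibitor	velvet-study:free
GP	Gly-Pro	ACE inhibitor	velvet-study:cryptide
GP	Gly-Pro	regulating	velvet-study:cryptide
GP	Gly-Pro	antiamnestic	velvet-study:cryptide
PG	Pro-Gly	ACE inhibitor	velvet-study:cryptide
PG	Pro-Gly	regulating	velvet-study:cryptide
PG	Pro-Gly	antiamnestic	velvet-study:cryptide
AG	Ala-Gly	ACE inhibitor	velvet-study:cryptide
PGP	Pro-Gly-Pro	regulating	velvet-study:cryptide
PGP	Pro-Gly-Pro	antiamnestic	velvet-study:cryptide
PGP	Pro-Gly-Pro	chemotactic	velvet-study:cryptide
PGP	Pro-Gly-Pro	anorectic	velvet-study:cryptide
VGAPG	Val-Gly-Ala-Pro-Gly	chemotactic	velvet-study:cryptide
VL	Val-Leu	stimulating	velvet-study:cryptide
LL	Leu-Leu	stimulating	velvet-study:cryptide
LV	Leu-Val	stimulating	velvet-study:cryptide
IL	Ile-Leu	stimulating	velvet-study:cryptide
LI	Leu-Ile	stimulating	velvet-study:cryptide
IV	Ile-Val	stimulating	velvet-study:cryptide
II	Ile-Ile	stimulating	velvet-study:cryptide
SE	Ser-Glu	stimulating	velvet-study:cryptide
VPL	Val-Pro-Leu	stimulating	velvet-study:cryptide
EEE	Glu-Glu-Glu	stimulating	velvet-study:cryptide
SSS	Ser-Ser-Ser	stimulating	velvet-study:cryptide
PLG	Gliadin 1 exorphin	opioid	velvet-study:cryptide
GLF	Gly-Leu-Phe	opioid	velvet-study:cryptide
TSKYR	Neokyotorphin	opioid	velvet-study:cryptide
YPWT	Hemorphin-4	opioid	velvet-study:cryptide
YPWTQ	Hemorphin-5	opioid	velvet-study:cryptide
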