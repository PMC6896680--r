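sequence	sample	fraction
VVYPWTQR	FDVA	ultrafiltrate
FLSFPTTK	FDVA	ultrafiltrate
FLSFPTTKTYFPH	FDVA	ultrafiltrate
SFPTTK	FDVA	ultrafiltrate
SFPTTKTYFPH	FDVA	ultrafiltrate
SFPTTKTYFPHFDLSHGSAQ	FDVA	ultrafiltrate
SFPTTKTYFPHFDLSHGSAQVK	FDVA	ultrafiltrate
TYFPH	FDVA	ultrafiltrate
TYFPHFDL	FDVA	ultrafiltrate
TYFPHFDLSH	FDVA	ultrafiltrate
TYFPHFDLSHG	FDVA	ultrafiltrate
TYFPHFDLSHGS	FDVA	ultrafiltrate
TYFPHFDLSHGSA	FDVA	ultrafiltrate
TYFPHFDLSHGSAQ	FDVA	ultrafiltrate
TYFPHFDLSHGSAQVK	FDVA	ultrafiltrate
SRAGLQFPVGRVH	FDVA	ultrafiltrate
QVSLNSGY	FDVA	ultrafiltrate
AAWGKVGGNAPAF	FDVA	ultrafiltrate
AAWGKVGGNAPAFGAE	FDVA	ultrafiltrate
LVVYPW	FDVA	ultrafiltrate
LVVYPWTQ	FDVA	ultrafiltrate
VVYPWTQ	FDVA	ultrafiltrate
SFPTTKTYFPHFDLSHG	DVA	ultrafiltrate
PTTKTYFPHFDLSH	DVA	ultrafiltrate
PTTKTYFPHFDLSHG	DVA	ultrafiltrate
TKTYFPHFDLSH	DVA	ultrafiltrate
TKTYFPHFDLSHG	DVA	ultrafiltrate
TYFPH	DVA	ultrafiltrate
TYFPHFDLSH	DVA	ultrafiltrate
TYFPHFDLSHG	DVA	ultrafiltrate
VLSAADKSNVK	DVA	ultrafiltrate
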