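# Cis-regulatory element motifs for IUPAC promoter scanning.
# Exact IUPAC consensus strings drawn from the primary literature; edit or
# replace freely -- this file is a convenience default, not a database.
name	pattern	category	citation
E-box	CANNTG	development	Ephrussi et al. 1985 Science 227:134; Toledo-Ortiz et al. 2003 Plant Cell 15:1749
G-box	CACGTG	light	Giuliano et al. 1988 PNAS 85:7089
ABRE	ACGTGGC	hormone	Busk & Pages 1998 Plant Mol Biol 37:425
LTR	CCGAAA	stress	Baker et al. 1994 Plant Mol Biol 24:701 (low-temperature responsive element)
MBS	CAACTG	stress	Urao et al. 1993 Plant Cell 5:1529 (MYB binding site)
ARE	AAACCA	stress	Walker et al. 1987 PNAS 84:6624 (anaerobic response element)
TGACG-motif	TGACG	hormone	Rouster et al. 1997 Plant J 11:513 (MeJA responsiveness)
I-box	GATAAG	light	Giuliano et al. 1988 PNAS 85:7089
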