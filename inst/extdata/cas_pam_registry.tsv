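# Curated Cas enzyme / PAM registry: 16 Cas9 + 5 Cas12a.
# pams and ranking_pams are comma-separated IUPAC patterns; an empty
# ranking_pams means all PAMs are used for segment ranking. xCas9 ranks by
# NG only because its GAA/GAT sites are already contained in the NG sites.
name	cas_type	pams	ranking_pams	citation
SpCas9	Cas9	NGG	NGG	Jinek et al. 2012
SpCas9-VQR	Cas9	NGA	NGA	Kleinstiver et al. 2015
EQR-SpCas9	Cas9	NGAG	NGAG	Kleinstiver et al. 2015
VRER-SpCas9	Cas9	NGCG	NGCG	Kleinstiver et al. 2015
SpCas9-NG	Cas9	NG	NG	Nishimasu et al. 2018
xCas9	Cas9	NG,GAA,GAT	NG	Hu et al. 2018
SpG	Cas9	NGN	NGN	Walton et al. 2020
SpRY	Cas9	NRN,NYN	NRN,NYN	Walton et al. 2020
SaCas9	Cas9	NNGRRT	NNGRRT	Ran et al. 2015
KKH-SaCas9	Cas9	NNNRRT	NNNRRT	Kleinstiver et al. 2015
St1Cas9	Cas9	NNAGAAW	NNAGAAW	Deveau et al. 2008
St3Cas9	Cas9	NGGNG	NGGNG	Horvath et al. 2008
NmCas9	Cas9	NNNNGATT	NNNNGATT	Hou et al. 2013
Nme2Cas9	Cas9	NNNNCC	NNNNCC	Edraki et al. 2019
CjCas9	Cas9	NNNNRYAC	NNNNRYAC	Kim et al. 2017
ScCas9	Cas9	NNG	NNG	Chatterjee et al. 2018
AsCas12a	Cas12a	TTTV	TTTV	Zetsche et al. 2015
LbCas12a	Cas12a	TTTV	TTTV	Zetsche et al. 2015
FnCas12a	Cas12a	TTTN,KYTV	TTTN,KYTV	Zetsche et al. 2015; Tu et al. 2017
enAsCas12a	Cas12a	TTYN,VTTV,TRTV	TTYN,VTTV,TRTV	Kleinstiver et al. 2019
RR-AsCas12a	Cas12a	TYCV	TYCV	Gao et al. 2017
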