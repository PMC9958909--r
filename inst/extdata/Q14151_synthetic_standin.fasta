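>Q14151_SYNTHETIC_STANDIN synthetic placeholder; NOT the native SAFB2 sequence (see README)
MHIRQILLRDTKGMQNVFQGGVGVIGDRRKSALVGGPDYVRRPNRNSAKAPNKSSTSCGS
LENHQTEGQDLDYMEAGQNLRHRLAGQMRGRLMAASEGTTSESDVTMVLAFMFVKLGGLP
CKIVTWICVGTCHGQRFTVMHTPQKHISRFTEYAMDSESHKEQRTIDKAYFGDIKDEAIP
ALDKALKAEFTHLGIIMTALLRARFNKSSIRIQSVGFKLAASVAREKQEFPKQDIPLLSY
TIDESGSFPCAIGANARTTEAGVQRYPTVPLATRADPAIIGSNFSTLKDEGPNAKQGGKK
SLHDERPIGVPYARIGELVERGPDQSKTNWRVNYQIHVCLSRDAASEEDAILTDVVDRLE
RKVAKLEMKRSRRAKTQHKKAINFLSVSRLYFGALSGMIKPVLGTRGNVWTLLAGFTLID
SILGNVVKFCYTNRDFDIKFNDFKEGARYLHPGSSTLNANNVETADDEYLKGFDAIYVYE
HFQHNLEKEALRAVLPVGFDAGFIVPAHPTAFSQVSGVDRVKGIRATIKPRLQKMVIEIL
QGELIVAVIQNETFKERAAAYPARSLKNLAEQDSLAQYIENIASINIIQDEVKPHVACAQ
LIEVPVSFLMQNSTGNRGNTDGGPVHEISRSSPYIPSQGFHRANEDSDELTVCTKSLEAG
TPHFAFQKIFGHCLMLVLDMAIIASGYGTSYLEIAVDVLSACTANVKRSCKEGILDVVLE
GDEFSVPIESLMIALVESNSKVILIPALHQAVMARKSYDVLDDHLKIFINELGPETKIHI
NVNKIYLLNALALTAADMVGIVAGELEEKRADAGTPKNVHIPSKGAIACMRKSQGWLKGP
TDETHGFQCNDEGTMSVDLERTVDSMLFFTAQAVRDMLLSESKATKNKKAVAIRFRNGFL
WKAHITIGVLPLSFAYLGQDIQREHEEGINTERLEEDIKFECVRMGSLTQGPG
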