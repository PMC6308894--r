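name	sequence	orientation	role
Uni-MinibarF1-d	TCYACTAATCATAAAGATATTGGYAC	forward	locus
Uni-MinibarR1-d	AAAATTATAATAAARGCRTGRGC	reverse	locus
ZBJ-ArtF1c	AGATATTGGAACWTTATATTTTATTTTTGG	forward	locus
ZBJ-ArtR2c	WACTAATCAATTWCCAAATCCTCC	reverse	locus
LepF1	ATTCAACCAATCATAAAGATATTGG	forward	locus
mLepR1	CCTGTTCCAGCTCCATTTT	reverse	locus
mlCOIintF	GGWACWGGWTGAACWGTWTAYCCYCC	forward	locus
jgHCO2198	TAIACYTCIGGRTGICCRAARAAYCA	reverse	locus
Sauron-S878	GGDRCWGGWTGAACWGTWTAYCCNCC	forward	locus
Sauron-Tail-S879	cacctgcttctaaatGGDRCWGGWTGAACWGTWTAYCCNCC	forward	tail1
jgHCO2198-Tail-A867	cacttcgactctttacTANACYTCNGGRTGNCCRAARAAYCA	reverse	tail1
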