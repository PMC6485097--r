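taxon	char	old	new	note
Aetomylaeus	9	0	0/1	postorbital process of neurocranium polymorphic
Myliobatis	16	*	0/1	fusion of jaw antimeres polymorphic (plesiomorphic condition in M. freminvillei)
Aetomylaeus	27	1	2	mesopterygium absent, possibly fused to scapulocoracoid
Weissobatis	27	*	1	mesopterygium fragmented
Rhinoptera	30	*	1	median prepelvic process greatly elongated
Mobula	30	*	1	median prepelvic process greatly elongated
Myliobatis	50	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Aetomylaeus	50	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Myliobatis	51	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Aetomylaeus	51	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Myliobatis	52	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Aetomylaeus	52	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Myliobatis	63	*	0/1	tooth character highly variable; member states not printed, 0/1 assumed
Rhinoptera	50	1	0	follows original description of the source matrix
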