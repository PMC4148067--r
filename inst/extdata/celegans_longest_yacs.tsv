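# Longest 15 YAC-exclusive segments of the C. elegans genome project.
# Coordinates are 1-based inclusive.
yac_id	chrom	start	end
Y73F8A	IV	15226338	15549111
Y105C5B	IV	15863724	16185028
Y105C5A	IV	15548990	15863827
Y57G11C	IV	14637373	14950845
Y75B8A	III	12069105	12367511
Y54G2A	IV	2750222	3036901
Y105E8A	I	14333265	14610766
Y51H4A	IV	16471836	16741455
Y116A8C	IV	16900192	17160330
Y111B2A	III	12492890	12750488
Y39B6A	V	18958057	19204189
Y53F4B	II	14951249	15178754
Y73B6BL	IV	6286329	6502271
Y47D3A	III	11136151	11335864
Y46G5A	II	12680715	12878522
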