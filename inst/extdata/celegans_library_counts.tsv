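# Published summary counts for the C. elegans genome-project clone libraries.
# coverage_bp: total genomic coverage of the library after YAC trimming.
# ncrna_21u: ncRNA genes that are 21U piRNAs; ncrna_excl_chrIV: ncRNA genes
# outside chromosome IV.
library	coverage_bp	cds	ncrna	trna	rrna	ncrna_21u	ncrna_excl_chrIV
cosmid	77668781	18071	11108	114	12	4713	6182
yac	22327861	3882	10799	94	10	9879	702
fosmid	1885889	325	817	NA	NA	NA	NA
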