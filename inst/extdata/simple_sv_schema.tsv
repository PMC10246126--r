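subcategory	major_class	qualifier	size_min	size_max	signature
DEL_fragile_site	deletion	fragile_site	1	Inf	Del2
TD_fragile_site	tandem_duplication	fragile_site	1	Inf	Del2
DEL_1_50	deletion	size_bin	1	50	Del0
DEL_50_100	deletion	size_bin	50	100	Del0
DEL_100_300	deletion	size_bin	100	300	Del0
DEL_300_1000	deletion	size_bin	300	1000	Del0
DEL_1000_2000	deletion	size_bin	1000	2000	Del1
DEL_2000_3000	deletion	size_bin	2000	3000	Del1
DEL_3000_5000	deletion	size_bin	3000	5000	Del1
DEL_5000_10000	deletion	size_bin	5000	10000	Del2
DEL_10000_30000	deletion	size_bin	10000	30000	Del2
DEL_30000_100000	deletion	size_bin	30000	100000	Del2
DEL_100000_300000	deletion	size_bin	100000	300000	Del2
DEL_300000_1000000	deletion	size_bin	300000	1000000	Del2
DEL_1000000_3000000	deletion	size_bin	1000000	3000000	Del2
DEL_3000000_10000000	deletion	size_bin	3000000	10000000	Del2
DEL_10000000_30000000	deletion	size_bin	10000000	30000000	Large mixed
DEL_30000000_100000000	deletion	size_bin	30000000	100000000	Large mixed
DEL_100000000_300000000	deletion	size_bin	100000000	300000000	Large mixed
DEL_300000000_Inf	deletion	size_bin	300000000	Inf	Large mixed
TD_1_1000	tandem_duplication	size_bin	1	1000	TD
TD_1000_5000	tandem_duplication	size_bin	1000	5000	TD
TD_5000_10000	tandem_duplication	size_bin	5000	10000	TD
TD_10000_50000	tandem_duplication	size_bin	10000	50000	TD
TD_50000_100000	tandem_duplication	size_bin	50000	100000	TD
TD_100000_250000	tandem_duplication	size_bin	100000	250000	TD
TD_250000_500000	tandem_duplication	size_bin	250000	500000	TD
TD_500000_1000000	tandem_duplication	size_bin	500000	1000000	TD
TD_1000000_1500000	tandem_duplication	size_bin	1000000	1500000	TD
TD_1500000_2000000	tandem_duplication	size_bin	1500000	2000000	TD
TD_2000000_2500000	tandem_duplication	size_bin	2000000	2500000	TD
TD_2500000_5000000	tandem_duplication	size_bin	2500000	5000000	TD
TD_5000000_7500000	tandem_duplication	size_bin	5000000	7500000	TD
TD_7500000_10000000	tandem_duplication	size_bin	7500000	10000000	TD
TD_10000000_30000000	tandem_duplication	size_bin	10000000	30000000	Large mixed
TD_30000000_100000000	tandem_duplication	size_bin	30000000	100000000	Large mixed
TD_100000000_300000000	tandem_duplication	size_bin	100000000	300000000	Large mixed
TD_300000000_Inf	tandem_duplication	size_bin	300000000	Inf	Large mixed
UINV_1_50000	inversion	unbalanced_size_bin	1	50000	Unbal inv
UINV_50000_5000000	inversion	unbalanced_size_bin	50000	5000000	Unbal inv
UINV_5000000_Inf	inversion	unbalanced_size_bin	5000000	Inf	Large mixed
RINV_1_10000	inversion	reciprocal_size_bin	1	10000	Recip
RINV_10000_100000	inversion	reciprocal_size_bin	10000	100000	Recip
RINV_100000_1000000	inversion	reciprocal_size_bin	100000	1000000	Recip
RINV_1000000_5000000	inversion	reciprocal_size_bin	1000000	5000000	Recip
RINV_5000000_Inf	inversion	reciprocal_size_bin	5000000	Inf	Large mixed
foldback_inversion	inversion	foldback	0	Inf	Unbal inv
reciprocal_translocation	translocation	reciprocal	0	Inf	Recip
unbalanced_translocation	translocation	unbalanced	0	Inf	Unbal tra
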