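# synthetic fixture: structure consistent with a pooled knock-in screen; not measured data
# coordinates: signed bp anchored at the predicted DSB (offset 0, blunt cut assumed 3 bp 5' of PAM); negative = 5' of cut
event_id	offset	side	state
ev_bi_725_16	-980	five_prime	wildtype
ev_bi_725_16	-725	five_prime	donor
ev_bi_725_16	-540	five_prime	donor
ev_bi_725_16	-319	five_prime	donor
ev_bi_725_16	-220	five_prime	donor
ev_bi_725_16	-152	five_prime	donor
ev_bi_725_16	-94	five_prime	donor
ev_bi_725_16	-64	five_prime	donor
ev_bi_725_16	16	three_prime	donor
ev_bi_725_16	45	three_prime	wildtype
ev_bi_725_16	83	three_prime	wildtype
ev_bi_725_16	149	three_prime	wildtype
ev_bi_725_16	220	three_prime	wildtype
ev_bi_725_16	319	three_prime	wildtype
ev_bi_725_16	600	three_prime	wildtype
ev_uni5_220	-980	five_prime	wildtype
ev_uni5_220	-725	five_prime	wildtype
ev_uni5_220	-540	five_prime	wildtype
ev_uni5_220	-319	five_prime	wildtype
ev_uni5_220	-220	five_prime	donor
ev_uni5_220	-152	five_prime	donor
ev_uni5_220	-94	five_prime	donor
ev_uni5_220	-64	five_prime	donor
ev_uni5_220	16	three_prime	wildtype
ev_uni5_220	45	three_prime	wildtype
ev_uni5_220	83	three_prime	wildtype
ev_uni5_220	149	three_prime	wildtype
ev_uni5_220	220	three_prime	wildtype
ev_uni5_220	319	three_prime	wildtype
ev_uni5_220	600	three_prime	wildtype
ev_uni3_149	-980	five_prime	wildtype
ev_uni3_149	-725	five_prime	wildtype
ev_uni3_149	-540	five_prime	wildtype
ev_uni3_149	-319	five_prime	wildtype
ev_uni3_149	-220	five_prime	wildtype
ev_uni3_149	-152	five_prime	wildtype
ev_uni3_149	-94	five_prime	wildtype
ev_uni3_149	-64	five_prime	wildtype
ev_uni3_149	16	three_prime	donor
ev_uni3_149	45	three_prime	donor
ev_uni3_149	83	three_prime	donor
ev_uni3_149	149	three_prime	donor
ev_uni3_149	220	three_prime	wildtype
ev_uni3_149	319	three_prime	wildtype
ev_uni3_149	600	three_prime	wildtype
ev_uni5_152	-980	five_prime	wildtype
ev_uni5_152	-725	five_prime	wildtype
ev_uni5_152	-540	five_prime	wildtype
ev_uni5_152	-319	five_prime	wildtype
ev_uni5_152	-220	five_prime	wildtype
ev_uni5_152	-152	five_prime	donor
ev_uni5_152	-94	five_prime	donor
ev_uni5_152	-64	five_prime	donor
ev_uni5_152	16	three_prime	wildtype
ev_uni5_152	45	three_prime	wildtype
ev_uni5_152	83	three_prime	wildtype
ev_uni5_152	149	three_prime	wildtype
ev_uni5_152	220	three_prime	wildtype
ev_uni5_152	319	three_prime	wildtype
ev_uni5_152	600	three_prime	wildtype
ev_non_a	-980	five_prime	wildtype
ev_non_a	-725	five_prime	wildtype
ev_non_a	-540	five_prime	wildtype
ev_non_a	-319	five_prime	wildtype
ev_non_a	-220	five_prime	wildtype
ev_non_a	-152	five_prime	wildtype
ev_non_a	-94	five_prime	wildtype
ev_non_a	-64	five_prime	wildtype
ev_non_a	16	three_prime	wildtype
ev_non_a	45	three_prime	wildtype
ev_non_a	83	three_prime	wildtype
ev_non_a	149	three_prime	wildtype
ev_non_a	220	three_prime	wildtype
ev_non_a	319	three_prime	wildtype
ev_non_a	600	three_prime	wildtype
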