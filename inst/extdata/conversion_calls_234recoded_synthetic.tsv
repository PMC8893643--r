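# synthetic fixture: structure consistent with a pooled knock-in screen; not measured data
# coordinates: signed bp anchored at the predicted DSB (offset 0, blunt cut assumed 3 bp 5' of PAM); negative = 5' of cut
event_id	offset	side	state
ev_bi_94_149	-700	five_prime	wildtype
ev_bi_94_149	-319	five_prime	wildtype
ev_bi_94_149	-220	five_prime	wildtype
ev_bi_94_149	-150	five_prime	wildtype
ev_bi_94_149	-94	five_prime	donor
ev_bi_94_149	-60	five_prime	donor
ev_bi_94_149	-30	five_prime	donor
ev_bi_94_149	57	three_prime	donor
ev_bi_94_149	90	three_prime	donor
ev_bi_94_149	149	three_prime	donor
ev_bi_94_149	220	three_prime	wildtype
ev_bi_94_149	319	three_prime	wildtype
ev_bi_94_149	610	three_prime	wildtype
ev_uni3_220	-700	five_prime	wildtype
ev_uni3_220	-319	five_prime	wildtype
ev_uni3_220	-220	five_prime	wildtype
ev_uni3_220	-150	five_prime	wildtype
ev_uni3_220	-94	five_prime	wildtype
ev_uni3_220	-60	five_prime	wildtype
ev_uni3_220	-30	five_prime	wildtype
ev_uni3_220	57	three_prime	donor
ev_uni3_220	90	three_prime	donor
ev_uni3_220	149	three_prime	donor
ev_uni3_220	220	three_prime	donor
ev_uni3_220	319	three_prime	wildtype
ev_uni3_220	610	three_prime	wildtype
ev_uni5_94	-700	five_prime	wildtype
ev_uni5_94	-319	five_prime	wildtype
ev_uni5_94	-220	five_prime	wildtype
ev_uni5_94	-150	five_prime	wildtype
ev_uni5_94	-94	five_prime	donor
ev_uni5_94	-60	five_prime	donor
ev_uni5_94	-30	five_prime	donor
ev_uni5_94	57	three_prime	wildtype
ev_uni5_94	90	three_prime	wildtype
ev_uni5_94	149	three_prime	wildtype
ev_uni5_94	220	three_prime	wildtype
ev_uni5_94	319	three_prime	wildtype
ev_uni5_94	610	three_prime	wildtype
ev_uni3_90	-700	five_prime	wildtype
ev_uni3_90	-319	five_prime	wildtype
ev_uni3_90	-220	five_prime	wildtype
ev_uni3_90	-150	five_prime	wildtype
ev_uni3_90	-94	five_prime	wildtype
ev_uni3_90	-60	five_prime	wildtype
ev_uni3_90	-30	five_prime	wildtype
ev_uni3_90	57	three_prime	donor
ev_uni3_90	90	three_prime	donor
ev_uni3_90	149	three_prime	wildtype
ev_uni3_90	220	three_prime	wildtype
ev_uni3_90	319	three_prime	wildtype
ev_uni3_90	610	three_prime	wildtype
ev_non_b	-700	five_prime	wildtype
ev_non_b	-319	five_prime	wildtype
ev_non_b	-220	five_prime	wildtype
ev_non_b	-150	five_prime	wildtype
ev_non_b	-94	five_prime	wildtype
ev_non_b	-60	five_prime	wildtype
ev_non_b	-30	five_prime	wildtype
ev_non_b	57	three_prime	wildtype
ev_non_b	90	three_prime	wildtype
ev_non_b	149	three_prime	wildtype
ev_non_b	220	three_prime	wildtype
ev_non_b	319	three_prime	wildtype
ev_non_b	610	three_prime	wildtype
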