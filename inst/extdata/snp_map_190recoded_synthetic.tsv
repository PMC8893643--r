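# synthetic fixture: structure consistent with a pooled knock-in screen; not measured data
# coordinates: signed bp anchored at the predicted DSB (offset 0, blunt cut assumed 3 bp 5' of PAM); negative = 5' of cut
offset	side	ref_base	donor_base
-980	five_prime	A	C
-725	five_prime	A	G
-540	five_prime	A	G
-319	five_prime	A	G
-220	five_prime	C	T
-152	five_prime	T	G
-94	five_prime	C	A
-64	five_prime	C	A
16	three_prime	A	T
45	three_prime	T	A
83	three_prime	G	T
149	three_prime	T	A
220	three_prime	G	A
319	three_prime	T	C
600	three_prime	A	T
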