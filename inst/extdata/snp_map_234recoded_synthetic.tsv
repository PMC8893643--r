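# synthetic fixture: structure consistent with a pooled knock-in screen; not measured data
# coordinates: signed bp anchored at the predicted DSB (offset 0, blunt cut assumed 3 bp 5' of PAM); negative = 5' of cut
offset	side	ref_base	donor_base
-700	five_prime	C	G
-319	five_prime	A	C
-220	five_prime	C	A
-150	five_prime	T	C
-94	five_prime	C	G
-60	five_prime	G	T
-30	five_prime	G	T
57	three_prime	C	A
90	three_prime	C	A
149	three_prime	T	C
220	three_prime	T	C
319	three_prime	T	C
610	three_prime	C	G
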