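# synthetic fixture: structure consistent with a pooled knock-in screen; not measured data
construct	donor_type	pool_id	n_founders	positive	g0_survivors_total
190-perfect	plasmid	190-perfect-01	20	1	271
190-perfect	plasmid	190-perfect-02	20	1	271
190-perfect	plasmid	190-perfect-03	20	1	271
190-perfect	plasmid	190-perfect-04	20	1	271
190-perfect	plasmid	190-perfect-05	20	1	271
190-perfect	plasmid	190-perfect-06	20	1	271
190-perfect	plasmid	190-perfect-07	20	1	271
190-perfect	plasmid	190-perfect-08	20	1	271
190-perfect	plasmid	190-perfect-09	20	1	271
190-perfect	plasmid	190-perfect-10	20	1	271
190-perfect	plasmid	190-perfect-11	20	1	271
190-perfect	plasmid	190-perfect-12	20	1	271
190-perfect	plasmid	190-perfect-13	20	1	271
64+234-perfect	plasmid	64+234-perfect-01	20	1	355
64+234-perfect	plasmid	64+234-perfect-02	20	1	355
64+234-perfect	plasmid	64+234-perfect-03	20	1	355
64+234-perfect	plasmid	64+234-perfect-04	20	1	355
64+234-perfect	plasmid	64+234-perfect-05	20	1	355
64+234-perfect	plasmid	64+234-perfect-06	20	1	355
64+234-perfect	plasmid	64+234-perfect-07	20	1	355
64+234-perfect	plasmid	64+234-perfect-08	20	1	355
64+234-perfect	plasmid	64+234-perfect-09	20	0	355
64+234-perfect	plasmid	64+234-perfect-10	20	0	355
64+234-perfect	plasmid	64+234-perfect-11	20	0	355
64+234-perfect	plasmid	64+234-perfect-12	20	0	355
64+234-perfect	plasmid	64+234-perfect-13	20	0	355
64+234-perfect	plasmid	64+234-perfect-14	20	0	355
64+234-perfect	plasmid	64+234-perfect-15	20	0	355
64+234-perfect	plasmid	64+234-perfect-16	20	0	355
64+234-perfect	plasmid	64+234-perfect-17	20	0	355
234-recoded	plasmid	234-recoded-01	20	1	339
234-recoded	plasmid	234-recoded-02	20	1	339
234-recoded	plasmid	234-recoded-03	20	1	339
234-recoded	plasmid	234-recoded-04	20	1	339
234-recoded	plasmid	234-recoded-05	20	1	339
234-recoded	plasmid	234-recoded-06	20	1	339
234-recoded	plasmid	234-recoded-07	20	1	339
234-recoded	plasmid	234-recoded-08	20	1	339
234-recoded	plasmid	234-recoded-09	20	0	339
234-recoded	plasmid	234-recoded-10	20	0	339
234-recoded	plasmid	234-recoded-11	20	0	339
234-recoded	plasmid	234-recoded-12	20	0	339
234-recoded	plasmid	234-recoded-13	20	0	339
234-recoded	plasmid	234-recoded-14	20	0	339
234-recoded	plasmid	234-recoded-15	20	0	339
234-recoded	plasmid	234-recoded-16	20	0	339
190-recoded	plasmid	190-recoded-01	20	1	184
190-recoded	plasmid	190-recoded-02	20	1	184
190-recoded	plasmid	190-recoded-03	20	1	184
190-recoded	plasmid	190-recoded-04	20	0	184
190-recoded	plasmid	190-recoded-05	20	0	184
190-recoded	plasmid	190-recoded-06	20	0	184
190-recoded	plasmid	190-recoded-07	20	0	184
190-recoded	plasmid	190-recoded-08	20	0	184
190-recoded	plasmid	190-recoded-09	20	0	184
190-recoded-ss	ssDNA	190-recoded-ss-01	20	1	174
190-recoded-ss	ssDNA	190-recoded-ss-02	20	1	174
190-recoded-ss	ssDNA	190-recoded-ss-03	20	0	174
190-recoded-ss	ssDNA	190-recoded-ss-04	20	0	174
190-recoded-ss	ssDNA	190-recoded-ss-05	20	0	174
190-recoded-ss	ssDNA	190-recoded-ss-06	20	0	174
190-recoded-ss	ssDNA	190-recoded-ss-07	20	0	174
190-recoded-ss	ssDNA	190-recoded-ss-08	20	0	174
190-recoded-bd	BTN-dsDNA	190-recoded-bd-01	20	1	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-02	20	1	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-03	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-04	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-05	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-06	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-07	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-08	20	0	184
190-recoded-bd	BTN-dsDNA	190-recoded-bd-09	20	0	184
190-recoded-bs	BTN-ssDNA	190-recoded-bs-01	20	1	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-02	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-03	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-04	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-05	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-06	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-07	20	0	178
190-recoded-bs	BTN-ssDNA	190-recoded-bs-08	20	0	178
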