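snp	gene	nu_l	species	unit	popsys	f
SNP1	adcy9	A	RR	Cit	all-R	0
SNP1	adcy9	A	RR	Zel	all-R	0
SNP1	adcy9	A	RR	Sur	all-R	0
SNP1	adcy9	A	RR	Kap	all-R	0
SNP1	adcy9	A	RR	Bul	all-R	0
SNP1	adcy9	A	RR	Olt	all-R	0
SNP1	adcy9	A	RR	Alb	all-R	0
SNP1	adcy9	A	RR	Dol	all-R	0
SNP1	adcy9	A	RR	Kos	all-R	0
SNP1	adcy9	A	RR	Kar	R-E	0.11
SNP1	adcy9	A	RR	Leb	R-E	0.08
SNP2	adcy9	C	RR	Cit	all-R	0
SNP2	adcy9	C	RR	Zel	all-R	0
SNP2	adcy9	C	RR	Sur	all-R	0
SNP2	adcy9	C	RR	Kap	all-R	0
SNP2	adcy9	C	RR	Bul	all-R	0
SNP2	adcy9	C	RR	Olt	all-R	0
SNP2	adcy9	C	RR	Alb	all-R	0
SNP2	adcy9	C	RR	Dol	all-R	0
SNP2	adcy9	C	RR	Kos	all-R	0
SNP2	adcy9	C	RR	Kar	R-E	0.11
SNP2	adcy9	C	RR	Leb	R-E	0.08
SNP24	hat1	C	RR	Cit	all-R	0.09
SNP24	hat1	C	RR	Zel	all-R	0
SNP24	hat1	C	RR	Sur	all-R	0
SNP24	hat1	C	RR	Kap	all-R	0
SNP24	hat1	C	RR	Bul	all-R	0
SNP24	hat1	C	RR	Olt	all-R	0
SNP24	hat1	C	RR	Alb	all-R	0
SNP24	hat1	C	RR	Dol	all-R	0
SNP24	hat1	C	RR	Kos	all-R	0
SNP24	hat1	C	RR	Kar	R-E	0
SNP24	hat1	C	RR	Leb	R-E	0
SNP25	henmt1	C	RR	Cit	all-R	0
SNP25	henmt1	C	RR	Zel	all-R	0
SNP25	henmt1	C	RR	Sur	all-R	0
SNP25	henmt1	C	RR	Kap	all-R	0
SNP25	henmt1	C	RR	Bul	all-R	0
SNP25	henmt1	C	RR	Olt	all-R	0
SNP25	henmt1	C	RR	Alb	all-R	0
SNP25	henmt1	C	RR	Dol	all-R	0
SNP25	henmt1	C	RR	Kos	all-R	0
SNP25	henmt1	C	RR	Kar	R-E	0
SNP25	henmt1	C	RR	Leb	R-E	0.02
SNP30	hormad1	C	RR	Cit	all-R	0
SNP30	hormad1	C	RR	Zel	all-R	0
SNP30	hormad1	C	RR	Sur	all-R	0
SNP30	hormad1	C	RR	Kap	all-R	0
SNP30	hormad1	C	RR	Bul	all-R	0
SNP30	hormad1	C	RR	Olt	all-R	0
SNP30	hormad1	C	RR	Alb	all-R	0
SNP30	hormad1	C	RR	Dol	all-R	0.04
SNP30	hormad1	C	RR	Kos	all-R	0
SNP30	hormad1	C	RR	Kar	R-E	0
SNP30	hormad1	C	RR	Leb	R-E	0.04
SNP32	hormad1	A	RR	Cit	all-R	0
SNP32	hormad1	A	RR	Zel	all-R	0
SNP32	hormad1	A	RR	Sur	all-R	0
SNP32	hormad1	A	RR	Kap	all-R	0
SNP32	hormad1	A	RR	Bul	all-R	0
SNP32	hormad1	A	RR	Olt	all-R	0
SNP32	hormad1	A	RR	Alb	all-R	0
SNP32	hormad1	A	RR	Dol	all-R	0.04
SNP32	hormad1	A	RR	Kos	all-R	0
SNP32	hormad1	A	RR	Kar	R-E	0
SNP32	hormad1	A	RR	Leb	R-E	0.04
SNP45	itpr1	T	RR	Cit	all-R	1
SNP45	itpr1	T	RR	Zel	all-R	1
SNP45	itpr1	T	RR	Sur	all-R	1
SNP45	itpr1	T	RR	Kap	all-R	1
SNP45	itpr1	T	RR	Bul	all-R	1
SNP45	itpr1	T	RR	Olt	all-R	1
SNP45	itpr1	T	RR	Alb	all-R	1
SNP45	itpr1	T	RR	Dol	all-R	1
SNP45	itpr1	T	RR	Kos	all-R	1
SNP45	itpr1	T	RR	Kar	R-E	1
SNP45	itpr1	T	RR	Leb	R-E	1
SNP61	map3k7	G	RR	Cit	all-R	0.04
SNP61	map3k7	G	RR	Zel	all-R	0
SNP61	map3k7	G	RR	Sur	all-R	0
SNP61	map3k7	G	RR	Kap	all-R	0
SNP61	map3k7	G	RR	Bul	all-R	0
SNP61	map3k7	G	RR	Olt	all-R	0
SNP61	map3k7	G	RR	Alb	all-R	0
SNP61	map3k7	G	RR	Dol	all-R	0
SNP61	map3k7	G	RR	Kos	all-R	0
SNP61	map3k7	G	RR	Kar	R-E	0
SNP61	map3k7	G	RR	Leb	R-E	0
SNP78	msh2	G	RR	Cit	all-R	1
SNP78	msh2	G	RR	Zel	all-R	1
SNP78	msh2	G	RR	Sur	all-R	1
SNP78	msh2	G	RR	Kap	all-R	1
SNP78	msh2	G	RR	Bul	all-R	1
SNP78	msh2	G	RR	Olt	all-R	0.72
SNP78	msh2	G	RR	Alb	all-R	1
SNP78	msh2	G	RR	Dol	all-R	1
SNP78	msh2	G	RR	Kos	all-R	1
SNP78	msh2	G	RR	Kar	R-E	1
SNP78	msh2	G	RR	Leb	R-E	1
SNP84	parn	G	RR	Cit	all-R	1
SNP84	parn	G	RR	Zel	all-R	1
SNP84	parn	G	RR	Sur	all-R	NA
SNP84	parn	G	RR	Kap	all-R	1
SNP84	parn	G	RR	Bul	all-R	1
SNP84	parn	G	RR	Olt	all-R	1
SNP84	parn	G	RR	Alb	all-R	1
SNP84	parn	G	RR	Dol	all-R	1
SNP84	parn	G	RR	Kos	all-R	1
SNP84	parn	G	RR	Kar	R-E	1
SNP84	parn	G	RR	Leb	R-E	1
SNP99	plk1	C	RR	Cit	all-R	0
SNP99	plk1	C	RR	Zel	all-R	0
SNP99	plk1	C	RR	Sur	all-R	0
SNP99	plk1	C	RR	Kap	all-R	0
SNP99	plk1	C	RR	Bul	all-R	0.06
SNP99	plk1	C	RR	Olt	all-R	0
SNP99	plk1	C	RR	Alb	all-R	0
SNP99	plk1	C	RR	Dol	all-R	0
SNP99	plk1	C	RR	Kos	all-R	0
SNP99	plk1	C	RR	Kar	R-E	0
SNP99	plk1	C	RR	Leb	R-E	0
SNP114	rbbp8	A	RR	Cit	all-R	0.05
SNP114	rbbp8	A	RR	Zel	all-R	0
SNP114	rbbp8	A	RR	Sur	all-R	0
SNP114	rbbp8	A	RR	Kap	all-R	0
SNP114	rbbp8	A	RR	Bul	all-R	0
SNP114	rbbp8	A	RR	Olt	all-R	0
SNP114	rbbp8	A	RR	Alb	all-R	0
SNP114	rbbp8	A	RR	Dol	all-R	0
SNP114	rbbp8	A	RR	Kos	all-R	0
SNP114	rbbp8	A	RR	Kar	R-E	0
SNP114	rbbp8	A	RR	Leb	R-E	0
SNP124	smc1a	C	RR	Cit	all-R	0
SNP124	smc1a	C	RR	Zel	all-R	0
SNP124	smc1a	C	RR	Sur	all-R	0.21
SNP124	smc1a	C	RR	Kap	all-R	0
SNP124	smc1a	C	RR	Bul	all-R	0
SNP124	smc1a	C	RR	Olt	all-R	0.06
SNP124	smc1a	C	RR	Alb	all-R	0
SNP124	smc1a	C	RR	Dol	all-R	0
SNP124	smc1a	C	RR	Kos	all-R	0
SNP124	smc1a	C	RR	Kar	R-E	0
SNP124	smc1a	C	RR	Leb	R-E	0
SNP125	smc1a	C	RR	Cit	all-R	0
SNP125	smc1a	C	RR	Zel	all-R	0
SNP125	smc1a	C	RR	Sur	all-R	0.21
SNP125	smc1a	C	RR	Kap	all-R	0
SNP125	smc1a	C	RR	Bul	all-R	0
SNP125	smc1a	C	RR	Olt	all-R	0.06
SNP125	smc1a	C	RR	Alb	all-R	0
SNP125	smc1a	C	RR	Dol	all-R	0
SNP125	smc1a	C	RR	Kos	all-R	0
SNP125	smc1a	C	RR	Kar	R-E	0
SNP125	smc1a	C	RR	Leb	R-E	0
SNP129	ywhaz	T	RR	Cit	all-R	0.95
SNP129	ywhaz	T	RR	Zel	all-R	1
SNP129	ywhaz	T	RR	Sur	all-R	1
SNP129	ywhaz	T	RR	Kap	all-R	1
SNP129	ywhaz	T	RR	Bul	all-R	1
SNP129	ywhaz	T	RR	Olt	all-R	1
SNP129	ywhaz	T	RR	Alb	all-R	1
SNP129	ywhaz	T	RR	Dol	all-R	1
SNP129	ywhaz	T	RR	Kos	all-R	1
SNP129	ywhaz	T	RR	Kar	R-E	1
SNP129	ywhaz	T	RR	Leb	R-E	1
SNP131	zfp36	C	RR	Cit	all-R	0
SNP131	zfp36	C	RR	Zel	all-R	0
SNP131	zfp36	C	RR	Sur	all-R	0
SNP131	zfp36	C	RR	Kap	all-R	0
SNP131	zfp36	C	RR	Bul	all-R	0
SNP131	zfp36	C	RR	Olt	all-R	0
SNP131	zfp36	C	RR	Alb	all-R	0
SNP131	zfp36	C	RR	Dol	all-R	0
SNP131	zfp36	C	RR	Kos	all-R	0
SNP131	zfp36	C	RR	Kar	R-E	0.05
SNP131	zfp36	C	RR	Leb	R-E	0.06
SNP1	adcy9	A	LL	Trn	L-E	1
SNP1	adcy9	A	LL	Cet	L-E	1
SNP1	adcy9	A	LL	Ger	L-E	1
SNP2	adcy9	C	LL	Trn	L-E	1
SNP2	adcy9	C	LL	Cet	L-E	1
SNP2	adcy9	C	LL	Ger	L-E	1
SNP24	hat1	C	LL	Trn	L-E	1
SNP24	hat1	C	LL	Cet	L-E	1
SNP24	hat1	C	LL	Ger	L-E	1
SNP25	henmt1	C	LL	Trn	L-E	1
SNP25	henmt1	C	LL	Cet	L-E	1
SNP25	henmt1	C	LL	Ger	L-E	1
SNP30	hormad1	C	LL	Trn	L-E	1
SNP30	hormad1	C	LL	Cet	L-E	1
SNP30	hormad1	C	LL	Ger	L-E	1
SNP32	hormad1	A	LL	Trn	L-E	1
SNP32	hormad1	A	LL	Cet	L-E	1
SNP32	hormad1	A	LL	Ger	L-E	1
SNP45	itpr1	T	LL	Trn	L-E	0.06
SNP45	itpr1	T	LL	Cet	L-E	0
SNP45	itpr1	T	LL	Ger	L-E	NA
SNP61	map3k7	G	LL	Trn	L-E	1
SNP61	map3k7	G	LL	Cet	L-E	1
SNP61	map3k7	G	LL	Ger	L-E	1
SNP78	msh2	G	LL	Trn	L-E	0
SNP78	msh2	G	LL	Cet	L-E	0
SNP78	msh2	G	LL	Ger	L-E	0
SNP84	parn	G	LL	Trn	L-E	0.05
SNP84	parn	G	LL	Cet	L-E	0
SNP84	parn	G	LL	Ger	L-E	NA
SNP99	plk1	C	LL	Trn	L-E	1
SNP99	plk1	C	LL	Cet	L-E	1
SNP99	plk1	C	LL	Ger	L-E	0.95
SNP114	rbbp8	A	LL	Trn	L-E	1
SNP114	rbbp8	A	LL	Cet	L-E	1
SNP114	rbbp8	A	LL	Ger	L-E	1
SNP124	smc1a	C	LL	Trn	L-E	1
SNP124	smc1a	C	LL	Cet	L-E	1
SNP124	smc1a	C	LL	Ger	L-E	1
SNP125	smc1a	C	LL	Trn	L-E	1
SNP125	smc1a	C	LL	Cet	L-E	1
SNP125	smc1a	C	LL	Ger	L-E	1
SNP129	ywhaz	T	LL	Trn	L-E	0
SNP129	ywhaz	T	LL	Cet	L-E	0
SNP129	ywhaz	T	LL	Ger	L-E	0
SNP131	zfp36	C	LL	Trn	L-E	1
SNP131	zfp36	C	LL	Cet	L-E	1
SNP131	zfp36	C	LL	Ger	L-E	1
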