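patient_id	gene	site	form	ref_base	alt_base	vaf	pop_freq	sift	polyphen2
P0001	TP53	TP53.site3	frameshift_inframe	NA	NA	0.257322246496004	0.00657643366104458	0.17538465433591	0.610371016104473
P0002	ARID1A	ARID1A.site3	frameshift_inframe	NA	NA	0.312446655072	0.000448179802391678	0.0139616300817579	0.808857363630086
P0002	BRAF	BRAF.site1	missense	T	C	0.369870812816453	NA	0.0139102014829405	0.488454481136054
P0003	EGFR	del19	frameshift_inframe	NA	NA	0.159139636775101	NA	NA	0.245356413768604
P0004	EGFR	del19	missense	T	A	0.161366433316169	NA	0.0129457443021238	0.902959973961581
P0004	EGFR	T790M	missense	C	T	0.0672520579615088	8.80656235385686e-05	0.0451669503818266	0.912317668513162
P0005	EGFR	L858R	missense	T	G	0.351413344472996	NA	0.491362838599598	0.274884854299482
P0005	EGFR	del19	nonstop	A	G	0.287698621537752	NA	0.0461191895185038	0.547320568948286
P0005	EGFR	T790M	missense	G	A	0.252884504258345	NA	0.847559132011374	0.539896395873045
P0005	TP53	TP53.site1	missense	C	A	0.201426201789019	NA	0.0407153916312382	0.667806837645592
P0005	BRAF	BRAF.site2	missense	C	T	0.165997953114653	NA	0.766637532203458	0.858053661786253
P0006	EGFR	del19	nonsense	C	T	0.209147460744066	0.000645931762410328	0.450427490338916	0.702140940597514
P0006	EGFR	T790M	missense	C	T	0.0931518434075855	NA	0.0434832817991264	0.721649399670307
P0006	EGFR	L858R	nonsense	T	C	0.151845708540741	NA	0.286062348866835	NA
P0006	TP53	TP53.site1	missense	C	T	0.0452199175555147	NA	NA	0.421800521202385
P0006	NRG1	NRG1.site1	frameshift_inframe	NA	NA	0.255321838121555	NA	0.00687311284709722	0.675935314179864
P0006	ARID1A	ARID1A.site3	frameshift_inframe	NA	NA	0.0101993402895446	NA	0.03607063353993	0.589639540000586
P0007	EGFR	del19	nonstop	C	A	0.0829833644229735	NA	0.0479681856930256	0.992568302204832
P0007	TP53	TP53.site3	nonsense	T	A	0.276223666517218	0.000738486566348001	0.230234766584355	0.517605635619955
P0008	EGFR	del19	missense	C	T	0.307482446647214	0.000645811628783122	0.0457631703116931	0.722515108255902
P0008	NTRK1	NTRK1.site2	missense	G	A	0.374276626378938	NA	0.907985711034853	0.992233366545755
P0009	EGFR	T790M	frameshift_inframe	NA	NA	0.281652176030146	NA	0.385584307251964	0.834867107715923
P0010	EGFR	del19	frameshift_inframe	NA	NA	0.145943661700444	NA	0.70924507511314	0.316958560368046
P0010	EGFR	L858R	missense	C	G	0.563208855700255	NA	0.129631869494915	NA
P0011	PIK3CA	PIK3CA.site1	missense	C	G	0.106080931331191	NA	0.0278662868775427	0.891876371165039
P0012	EGFR	L718Q	missense	T	G	0.358536774943669	NA	0.866992035839939	0.747374693583231
P0012	EGFR	L858R	missense	A	T	0.275445001959884	NA	0.0255240408936515	0.521444872696884
P0012	NRG1	NRG1.site2	missense	G	T	0.20596588540488	NA	0.91556647598953	0.595419467780273
P0012	POLE	POLE.site2	missense	C	T	0.244184269557595	NA	NA	0.254644265165552
P0013	EGFR	L858R	missense	T	A	0.159972330161337	NA	0.175262756512035	0.920150495090755
P0013	EGFR	del19	nonsense	A	T	0.28294019463327	4.07811619807035e-05	0.0229635116062127	0.782788439595839
P0014	EGFR	del19	frameshift_inframe	NA	NA	0.364172689163129	NA	NA	0.728541657095775
P0014	EGFR	C797S	missense	C	A	0.0444728650343819	NA	0.558810972943902	0.897455274639418
P0014	TP53	TP53.site1	frameshift_inframe	NA	NA	0.0746726008223491	NA	0.633706297492608	NA
P0015	EGFR	L858R	splicing	NA	NA	0.0692110128491394	NA	0.039451935258694	0.639223325825296
P0015	TP53	TP53.site3	missense	A	G	0.50802903452849	0.000797293595504016	NA	0.789208768401295
P0015	PIK3CA	PIK3CA.site2	frameshift_inframe	NA	NA	0.181031249171731	NA	0.0379817165550776	0.449317058930872
P0016	TP53	TP53.site3	frameshift_inframe	NA	NA	0.499633532374696	0.000820222070207819	0.036134900234174	0.699685936407885
P0018	TP53	TP53.site3	missense	G	A	0.100034023387138	NA	0.0325525977066718	0.498907207973534
P0019	ATM	ATM.site2	frameshift_inframe	NA	NA	0.265652648737165	NA	0.045481047895737	0.474613453078317
P0019	POLE	POLE.site1	missense	C	A	0.273851732528129	NA	0.0219243867439218	0.818117198453518
P0020	EGFR	del19	missense	G	T	0.0924025092809296	3.05936725344509e-05	0.777114518950693	0.0398642852031626
P0020	NRG1	NRG1.site1	missense	G	A	0.216103521893863	NA	0.259805557102663	0.521713287035236
P0021	EGFR	L858R	nonsense	A	G	0.374636500651822	NA	0.125380772864446	NA
P0021	TP53	TP53.site2	frameshift_inframe	NA	NA	0.223635741239586	NA	0.022415664838627	0.76819191727112
P0022	EGFR	L718Q	missense	T	C	0.224042343458475	NA	NA	0.794196061091498
P0022	TP53	TP53.site2	missense	C	G	0.252636243314832	NA	0.660942029155558	0.411193726642523
P0023	EGFR	del19	missense	A	G	0.222514134176302	NA	NA	0.597240240313113
P0023	EGFR	T790M	missense	T	C	0.25534743755482	NA	0.526284881342668	0.740391578383278
P0023	EGFR	L858R	frameshift_inframe	NA	NA	0.153317746593531	NA	0.223566114901798	0.740370133922901
P0024	EGFR	L858R	missense	C	T	0.343774641495381	NA	0.396356004160829	0.492960426913574
P0024	EGFR	del19	frameshift_inframe	NA	NA	0.271653012325885	0.000982077616499737	0.929540043956134	0.648604607712477
P0024	TP53	TP53.site2	missense	C	T	0.206151055986096	5.15921104233712e-05	NA	0.610517289489508
P0025	EGFR	L858R	missense	C	T	0.165738453305845	NA	0.494210433659609	0.363014248931315
P0025	EGFR	del19	missense	C	T	0.0216036952686232	NA	0.840753488539485	0.452775725977728
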