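sample_id	mean_met	mean_cep7
S001	1.8	2.48
S002	2.84	2.04
S003	2.38	2.06
S004	1.94	1.82
S005	2.12	2.02
S006	2.12	2.26
S007	7.72	2.74
S008	1.7	2.16
S009	2	2.02
S010	2.06	2.32
S011	3.48	3.24
S012	2.14	1.82
S013	2.18	2.08
S014	2.06	2.46
S015	2.24	2.12
S016	5.22	2.14
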