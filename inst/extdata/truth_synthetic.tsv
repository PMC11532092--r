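sample_id	truth
S001	NEGATIVE
S002	AMPLIFICATION
S003	NEGATIVE
S004	NEGATIVE
S005	NEGATIVE
S006	NEGATIVE
S007	AMPLIFICATION
S008	NEGATIVE
S009	NEGATIVE
S010	NEGATIVE
S011	POLYSOMY
S012	NEGATIVE
S013	NEGATIVE
S014	NEGATIVE
S015	NEGATIVE
S016	AMPLIFICATION
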