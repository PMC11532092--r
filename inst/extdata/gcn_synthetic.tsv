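sample_id	MET	EGFR	BRAF	CDK6	PMS2	ABCB1	CYP3A4
S001	1.9181116077871847	1.6455444614522041	2.0083052729418536	1.8147910162373775	2.2773553831292128	1.8697884660994948	2.1135741640214563
S002	3.2557157746562990	2.2320604341545809	2.1311454184974190	2.0408740387396636	2.2922014953144370	2.5179069344177925	2.2040411168527472
S003	1.6476975503190079	2.0558962836420283	1.9448484454768746	1.8592192136196124	1.8584829143089849	1.8135589245656329	1.9008612837043526
S004	1.6997887482375351	2.0829037373306418	2.1785029347031504	2.0701258256445136	1.8628547384641398	1.8319214132466084	2.1062968699168909
S005	1.8654665050497359	1.7652371002975480	2.0102807294047107	1.8513058965402105	2.0508976287736980	1.6891843627632805	1.8865256980482508
S006	2.1994602628884223	2.0382660040395337	1.8525831180223153	2.0882994083015345	1.9883746952075041	1.7237700037724184	1.9177166744529950
S007	7.8664210446260414	2.3719832408191510	2.3680250495831010	1.9821087116552558	2.3236385591482245	2.1586678415621607	2.1938271341501645
S008	2.1045984863447611	1.6761566118416660	1.9099941711513340	1.9514097374887105	2.2261579880685236	1.9571680895955481	2.0957126096126122
S009	1.8441013512343085	1.9601020680380454	1.8209480467070926	1.9551607546939780	2.1386699042152997	2.0237891248033115	2.1237200869638264
S010	1.8652489418932483	1.7776445675811678	2.0796517857480139	1.9279369325405007	2.1371887516065935	1.8262673503904860	1.8562852727322348
S011	3.2372028453011898	3.1883534919544778	3.0833011238260504	3.0617650286492801	2.9807708713808569	3.3840699736888817	3.2175492310586455
S012	2.2109683040519976	1.7199945804348129	1.9969416124266901	2.1228490863339347	2.0070558986263656	1.8181766591711268	2.0256249076862578
S013	1.8204095545920771	2.1617356218653558	1.8715756953116507	2.0501707272292600	2.1198992976575384	1.9938416546510183	1.9058601296305167
S014	2.3191680654843116	2.0172233085302516	1.7846433886323019	2.3148923829406050	2.0764562361485219	2.1262091955952900	2.4682450997703973
S015	1.8754640945470917	2.0582507965301393	2.0058468435651191	1.9057494467005274	1.9498519551576683	2.0338101877907420	1.7297768100342785
S016	6.0824230533548889	2.5305628372278224	2.4073174383148568	2.0381847433629199	2.4672297483630112	2.4101281011346223	2.4235551697247524
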