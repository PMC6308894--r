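seq_id	species	order	class
SYN0001	GenusA species01	orderA1	classA
SYN0002	GenusA species02	orderA2	classA
SYN0003	GenusA species03	orderA1	classA
SYN0004	GenusA species04	orderA2	classA
SYN0005	GenusA species05	orderA1	classA
SYN0006	GenusA species06	orderA2	classA
SYN0007	GenusA species07	orderA1	classA
SYN0008	GenusA species08	orderA2	classA
SYN0009	GenusA species09	orderA1	classA
SYN0010	GenusA species10	orderA2	classA
SYN0011	GenusA species11	orderA1	classA
SYN0012	GenusA species12	orderA2	classA
SYN0013	GenusA species13	orderA1	classA
SYN0014	GenusA species14	orderA2	classA
SYN0015	GenusA species15	orderA1	classA
SYN0016	GenusA species16	orderA2	classA
SYN0017	GenusA species17	orderA1	classA
SYN0018	GenusA species18	orderA2	classA
SYN0019	GenusA species19	orderA1	classA
SYN0020	GenusA species20	orderA2	classA
SYN0021	GenusB species01	orderB1	classB
SYN0022	GenusB species02	orderB2	classB
SYN0023	GenusB species03	orderB1	classB
SYN0024	GenusB species04	orderB2	classB
SYN0025	GenusB species05	orderB1	classB
SYN0026	GenusB species06	orderB2	classB
SYN0027	GenusB species07	orderB1	classB
SYN0028	GenusB species08	orderB2	classB
SYN0029	GenusB species09	orderB1	classB
SYN0030	GenusB species10	orderB2	classB
SYN0031	GenusB species11	orderB1	classB
SYN0032	GenusB species12	orderB2	classB
SYN0033	GenusB species13	orderB1	classB
SYN0034	GenusB species14	orderB2	classB
SYN0035	GenusB species15	orderB1	classB
SYN0036	GenusB species16	orderB2	classB
SYN0037	GenusB species17	orderB1	classB
SYN0038	GenusB species18	orderB2	classB
SYN0039	GenusB species19	orderB1	classB
SYN0040	GenusB species20	orderB2	classB
SYN0041	GenusC species01	orderC1	classC
SYN0042	GenusC species02	orderC2	classC
SYN0043	GenusC species03	orderC1	classC
SYN0044	GenusC species04	orderC2	classC
SYN0045	GenusC species05	orderC1	classC
SYN0046	GenusC species06	orderC2	classC
SYN0047	GenusC species07	orderC1	classC
SYN0048	GenusC species08	orderC2	classC
SYN0049	GenusC species09	orderC1	classC
SYN0050	GenusC species10	orderC2	classC
SYN0051	GenusC species11	orderC1	classC
SYN0052	GenusC species12	orderC2	classC
SYN0053	GenusC species13	orderC1	classC
SYN0054	GenusC species14	orderC2	classC
SYN0055	GenusC species15	orderC1	classC
SYN0056	GenusC species16	orderC2	classC
SYN0057	GenusC species17	orderC1	classC
SYN0058	GenusC species18	orderC2	classC
SYN0059	GenusC species19	orderC1	classC
SYN0060	GenusC species20	orderC2	classC
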