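stemness_synthetic	synthetic 109-entry placeholder for the externally defined stemness panel	STEM001	STEM002	STEM003	STEM004	STEM005	STEM006	STEM007	STEM008	STEM009	STEM010	STEM011	STEM012	STEM013	STEM014	STEM015	STEM016	STEM017	STEM018	STEM019	STEM020	STEM021	STEM022	STEM023	STEM024	STEM025	STEM026	STEM027	STEM028	STEM029	STEM030	STEM031	STEM032	STEM033	STEM034	STEM035	STEM036	STEM037	STEM038	STEM039	STEM040	STEM041	STEM042	STEM043	STEM044	STEM045	STEM046	STEM047	STEM048	STEM049	STEM050	STEM051	STEM052	STEM053	STEM054	STEM055	STEM056	STEM057	STEM058	STEM059	STEM060	STEM061	STEM062	STEM063	STEM064	STEM065	STEM066	STEM067	STEM068	STEM069	STEM070	STEM071	STEM072	STEM073	STEM074	STEM075	STEM076	STEM077	STEM078	STEM079	STEM080	STEM081	STEM082	STEM083	STEM084	STEM085	STEM086	STEM087	STEM088	STEM089	STEM090	STEM091	STEM092	STEM093	STEM094	STEM095	STEM096	STEM097	STEM098	STEM099	STEM100	STEM101	STEM102	STEM103	STEM104	STEM105	STEM106	STEM107	STEM108	STEM109
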