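g01_p001	g02_p001	91	200	10	1	1	200	1	200	1e-50	901
g01_p001	g03_p001	91	200	10	1	1	200	1	200	1e-50	901
g02_p001	g01_p001	91	200	10	1	1	200	1	200	1e-50	901
g02_p001	g03_p001	91	200	10	1	1	200	1	200	1e-50	901
g03_p001	g01_p001	91	200	10	1	1	200	1	200	1e-50	901
g03_p001	g02_p001	91	200	10	1	1	200	1	200	1e-50	901
g01_p002	g02_p002	92	200	10	1	1	200	1	200	1e-50	902
g01_p002	g03_p002	92	200	10	1	1	200	1	200	1e-50	902
g02_p002	g01_p002	92	200	10	1	1	200	1	200	1e-50	902
g02_p002	g03_p002	92	200	10	1	1	200	1	200	1e-50	902
g03_p002	g01_p002	92	200	10	1	1	200	1	200	1e-50	902
g03_p002	g02_p002	92	200	10	1	1	200	1	200	1e-50	902
g01_p003	g02_p003	93	200	10	1	1	200	1	200	1e-50	903
g01_p003	g03_p003	93	200	10	1	1	200	1	200	1e-50	903
g02_p003	g01_p003	93	200	10	1	1	200	1	200	1e-50	903
g02_p003	g03_p003	93	200	10	1	1	200	1	200	1e-50	903
g03_p003	g01_p003	93	200	10	1	1	200	1	200	1e-50	903
g03_p003	g02_p003	93	200	10	1	1	200	1	200	1e-50	903
g01_p004	g02_p004	94	200	10	1	1	200	1	200	1e-50	904
g01_p004	g03_p004	94	200	10	1	1	200	1	200	1e-50	904
g02_p004	g01_p004	94	200	10	1	1	200	1	200	1e-50	904
g02_p004	g03_p004	94	200	10	1	1	200	1	200	1e-50	904
g03_p004	g01_p004	94	200	10	1	1	200	1	200	1e-50	904
g03_p004	g02_p004	94	200	10	1	1	200	1	200	1e-50	904
g01_p005	g02_p005	95	200	10	1	1	200	1	200	1e-50	905
g01_p005	g03_p005	95	200	10	1	1	200	1	200	1e-50	905
g02_p005	g01_p005	95	200	10	1	1	200	1	200	1e-50	905
g02_p005	g03_p005	95	200	10	1	1	200	1	200	1e-50	905
g03_p005	g01_p005	95	200	10	1	1	200	1	200	1e-50	905
g03_p005	g02_p005	95	200	10	1	1	200	1	200	1e-50	905
g01_p006	g01_p007	86	200	10	1	1	200	1	200	1e-30	601
g01_p006	g01_p008	86	200	10	1	1	200	1	200	1e-30	601
g01_p007	g01_p006	86	200	10	1	1	200	1	200	1e-30	601
g01_p007	g01_p008	86	200	10	1	1	200	1	200	1e-30	601
g01_p008	g01_p006	86	200	10	1	1	200	1	200	1e-30	601
g01_p008	g01_p007	86	200	10	1	1	200	1	200	1e-30	601
g01_p009	g01_p010	87	200	10	1	1	200	1	200	1e-30	602
g01_p010	g01_p009	87	200	10	1	1	200	1	200	1e-30	602
g02_p006	g02_p007	86	200	10	1	1	200	1	200	1e-30	601
g02_p006	g02_p008	86	200	10	1	1	200	1	200	1e-30	601
g02_p007	g02_p006	86	200	10	1	1	200	1	200	1e-30	601
g02_p007	g02_p008	86	200	10	1	1	200	1	200	1e-30	601
g02_p008	g02_p006	86	200	10	1	1	200	1	200	1e-30	601
g02_p008	g02_p007	86	200	10	1	1	200	1	200	1e-30	601
g02_p009	g02_p010	87	200	10	1	1	200	1	200	1e-30	602
g02_p010	g02_p009	87	200	10	1	1	200	1	200	1e-30	602
g03_p006	g03_p007	86	200	10	1	1	200	1	200	1e-30	601
g03_p006	g03_p008	86	200	10	1	1	200	1	200	1e-30	601
g03_p007	g03_p006	86	200	10	1	1	200	1	200	1e-30	601
g03_p007	g03_p008	86	200	10	1	1	200	1	200	1e-30	601
g03_p008	g03_p006	86	200	10	1	1	200	1	200	1e-30	601
g03_p008	g03_p007	86	200	10	1	1	200	1	200	1e-30	601
g03_p009	g03_p010	87	200	10	1	1	200	1	200	1e-30	602
g03_p010	g03_p009	87	200	10	1	1	200	1	200	1e-30	602
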