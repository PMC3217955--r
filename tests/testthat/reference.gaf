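!gaf-version: 2.0
!generated-by: orthogo (synthetic fixture)
g01	g01_p002	g01_p002		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p002	g01_p002		GO:0000009	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p002	g01_p002		GO:0000029	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p003	g01_p003		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p003	g01_p003		GO:0000029	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p004	g01_p004		GO:0000012	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p005	g01_p005		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p007	g01_p007		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p007	g01_p007		GO:0000010	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p007	g01_p007		GO:0000013	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p007	g01_p007		GO:0000045	ORTHOGO:0000001	IEA		C			protein	taxon:0	20110101	orthogo		
g01	g01_p008	g01_p008		GO:0000039	ORTHOGO:0000001	IEA		C			protein	taxon:0	20110101	orthogo		
g01	g01_p009	g01_p009		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p010	g01_p010		GO:0000025	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p011	g01_p011		GO:0000012	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p011	g01_p011		GO:0000028	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p012	g01_p012		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p013	g01_p013		GO:0000042	ORTHOGO:0000001	IEA		C			protein	taxon:0	20110101	orthogo		
g01	g01_p015	g01_p015		GO:0000025	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p015	g01_p015		GO:0000039	ORTHOGO:0000001	IEA		C			protein	taxon:0	20110101	orthogo		
g01	g01_p016	g01_p016		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p017	g01_p017		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p017	g01_p017		GO:0000027	ORTHOGO:0000001	IEA		F			protein	taxon:0	20110101	orthogo		
g01	g01_p018	g01_p018		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p019	g01_p019		GO:0000008	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
g01	g01_p020	g01_p020		GO:0000015	ORTHOGO:0000001	IEA		P			protein	taxon:0	20110101	orthogo		
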