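TOY_MHC_BINDING_LIKE	synthetic toy term for pipeline tests	GENE_0296	GENE_0543	GENE_0383	GENE_0211	GENE_0573	GENE_0223	GENE_0300	GENE_0121	GENE_0345	GENE_0153	GENE_0167	GENE_0415	GENE_0419	GENE_0206	GENE_0400	GENE_0045	GENE_0480	GENE_0041	GENE_0409	GENE_0463	GENE_0343	GENE_0088	GENE_0119	GENE_0411	GENE_0209	GENE_0502	GENE_0076	GENE_0053	GENE_0266	GENE_0493	GENE_0368	GENE_0456	GENE_0169	GENE_0362	GENE_0243	GENE_0437	GENE_0556	GENE_0277	GENE_0188	GENE_0451	GENE_0232	GENE_0049	GENE_0192	GENE_0177	GENE_0417	GENE_0398	GENE_0110	GENE_0372	GENE_0011	GENE_0308	GENE_0488	GENE_0455
TOY_CYTOKINE_ACTIVITY_LIKE	synthetic toy term for pipeline tests	GENE_0014	GENE_0445	GENE_0289	GENE_0409	GENE_0030	GENE_0250	GENE_0352	GENE_0091	GENE_0175	GENE_0391	GENE_0302	GENE_0163	GENE_0073	GENE_0101	GENE_0249	GENE_0274	GENE_0190	GENE_0235	GENE_0503	GENE_0075	GENE_0467	GENE_0221	GENE_0396	GENE_0038	GENE_0171	GENE_0329	GENE_0004	GENE_0334	GENE_0479	GENE_0040	GENE_0090	GENE_0167	GENE_0032	GENE_0084	GENE_0252	GENE_0039	GENE_0577	GENE_0433	GENE_0139	GENE_0245	GENE_0450	GENE_0189	GENE_0059	GENE_0339	GENE_0417	GENE_0115	GENE_0428	GENE_0207	GENE_0083	GENE_0502	GENE_0322	GENE_0182	GENE_0522	GENE_0146	GENE_0354	GENE_0079	GENE_0187
TOY_TNF_RECEPTOR_BINDING_LIKE	synthetic toy term for pipeline tests	GENE_0019	GENE_0204	GENE_0458	GENE_0446	GENE_0325	GENE_0363	GENE_0564	GENE_0247	GENE_0241	GENE_0226	GENE_0082	GENE_0249	GENE_0346	GENE_0544	GENE_0304	GENE_0409	GENE_0284	GENE_0315	GENE_0221	GENE_0336	GENE_0412	GENE_0554	GENE_0173	GENE_0091	GENE_0225	GENE_0463	GENE_0378	GENE_0447	GENE_0122	GENE_0067	GENE_0323	GENE_0513	GENE_0117	GENE_0164	GENE_0231	GENE_0311	GENE_0377	GENE_0383	GENE_0494	GENE_0558	GENE_0508	GENE_0149	GENE_0504	GENE_0276	GENE_0477
TOY_CHEMOKINE_RECEPTOR_LIKE	synthetic toy term for pipeline tests	GENE_0009	GENE_0434	GENE_0080	GENE_0245	GENE_0549	GENE_0138	GENE_0035	GENE_0238	GENE_0541	GENE_0357	GENE_0422	GENE_0253	GENE_0221	GENE_0142	GENE_0361	GENE_0468	GENE_0368	GENE_0323	GENE_0304	GENE_0545	GENE_0254	GENE_0440	GENE_0345	GENE_0321	GENE_0338	GENE_0449	GENE_0551	GENE_0122	GENE_0555	GENE_0417	GENE_0414
TOY_LYMPHOCYTE_ACTIVATION_LIKE	synthetic toy term for pipeline tests	GENE_0054	GENE_0546	GENE_0169	GENE_0045	GENE_0511	GENE_0460	GENE_0025	GENE_0428	GENE_0528	GENE_0215	GENE_0385	GENE_0170	GENE_0504	GENE_0431	GENE_0237	GENE_0549	GENE_0175	GENE_0106	GENE_0477	GENE_0265	GENE_0033	GENE_0251	GENE_0202	GENE_0107	GENE_0384	GENE_0570	GENE_0002	GENE_0510	GENE_0009	GENE_0037	GENE_0119	GENE_0031	GENE_0408	GENE_0224	GENE_0556	GENE_0087	GENE_0436	GENE_0526	GENE_0268	GENE_0137
TOY_ADAPTIVE_IMMUNE_LIKE	synthetic toy term for pipeline tests	GENE_0502	GENE_0534	GENE_0086	GENE_0134	GENE_0215	GENE_0420	GENE_0529	GENE_0350	GENE_0294	GENE_0259	GENE_0207	GENE_0349	GENE_0017	GENE_0148	GENE_0209	GENE_0316	GENE_0051	GENE_0179	GENE_0025	GENE_0217	GENE_0103	GENE_0155	GENE_0107	GENE_0358	GENE_0192	GENE_0039	GENE_0505	GENE_0034	GENE_0171	GENE_0383	GENE_0412	GENE_0354	GENE_0521	GENE_0197	GENE_0231	GENE_0441	GENE_0004	GENE_0542	GENE_0460	GENE_0068	GENE_0162	GENE_0282	GENE_0010	GENE_0568	GENE_0527	GENE_0515	GENE_0105	GENE_0169	GENE_0434	GENE_0076	GENE_0234	GENE_0492	GENE_0504	GENE_0401	GENE_0166	GENE_0219	GENE_0432	GENE_0038
TOY_ANTIGEN_PROCESSING_LIKE	synthetic toy term for pipeline tests	GENE_0051	GENE_0427	GENE_0128	GENE_0203	GENE_0289	GENE_0528	GENE_0196	GENE_0365	GENE_0126	GENE_0295	GENE_0524	GENE_0275	GENE_0237	GENE_0324	GENE_0420	GENE_0439	GENE_0136	GENE_0376	GENE_0508	GENE_0309	GENE_0026	GENE_0257	GENE_0380	GENE_0415	GENE_0099	GENE_0390	GENE_0316
TOY_INFLAMMATORY_RESPONSE_LIKE	synthetic toy term for pipeline tests	GENE_0162	GENE_0555	GENE_0559	GENE_0141	GENE_0522	GENE_0259	GENE_0221	GENE_0160	GENE_0103	GENE_0055	GENE_0012	GENE_0117	GENE_0344	GENE_0065	GENE_0441	GENE_0013	GENE_0437	GENE_0456	GENE_0033	GENE_0108	GENE_0373	GENE_0115	GENE_0300	GENE_0207	GENE_0020	GENE_0301
TOY_COMPLEMENT_LIKE	synthetic toy term for pipeline tests	GENE_0494	GENE_0244	GENE_0117	GENE_0039	GENE_0085	GENE_0118	GENE_0496	GENE_0537	GENE_0474	GENE_0068	GENE_0523	GENE_0522	GENE_0322	GENE_0236	GENE_0275	GENE_0530	GENE_0227	GENE_0331	GENE_0293	GENE_0521	GENE_0402	GENE_0302	GENE_0140	GENE_0542	GENE_0007	GENE_0556	GENE_0509	GENE_0301	GENE_0555	GENE_0136
TOY_LEUKOCYTE_MIGRATION_LIKE	synthetic toy term for pipeline tests	GENE_0525	GENE_0259	GENE_0393	GENE_0446	GENE_0578	GENE_0029	GENE_0389	GENE_0384	GENE_0559	GENE_0272	GENE_0347	GENE_0385	GENE_0266	GENE_0486	GENE_0292	GENE_0063	GENE_0008	GENE_0068	GENE_0382	GENE_0224	GENE_0322	GENE_0239	GENE_0579	GENE_0097	GENE_0439	GENE_0479	GENE_0275	GENE_0027	GENE_0180	GENE_0105	GENE_0430	GENE_0015	GENE_0437	GENE_0359	GENE_0171	GENE_0518	GENE_0149	GENE_0023
TOY_IL12_PATHWAY_LIKE	synthetic toy term for pipeline tests	GENE_0292	GENE_0380	GENE_0005	GENE_0218	GENE_0460	GENE_0442	GENE_0355	GENE_0532	GENE_0431	GENE_0567	GENE_0432	GENE_0388	GENE_0359	GENE_0215	GENE_0443	GENE_0179	GENE_0075	GENE_0249	GENE_0092	GENE_0025	GENE_0014	GENE_0400	GENE_0233	GENE_0453	GENE_0210	GENE_0377	GENE_0187	GENE_0022	GENE_0250	GENE_0547	GENE_0221	GENE_0208	GENE_0342	GENE_0298	GENE_0338	GENE_0044	GENE_0263	GENE_0271	GENE_0369	GENE_0057	GENE_0261	GENE_0330	GENE_0362	GENE_0541	GENE_0237
TOY_IL23_PATHWAY_LIKE	synthetic toy term for pipeline tests	GENE_0277	GENE_0402	GENE_0524	GENE_0276	GENE_0396	GENE_0060	GENE_0202	GENE_0335	GENE_0197	GENE_0410	GENE_0129	GENE_0575	GENE_0356	GENE_0033	GENE_0111	GENE_0348	GENE_0271	GENE_0547	GENE_0478	GENE_0085	GENE_0235	GENE_0508	GENE_0456	GENE_0263	GENE_0403	GENE_0195	GENE_0274	GENE_0495	GENE_0413	GENE_0301	GENE_0125	GENE_0338	GENE_0049	GENE_0446	GENE_0001	GENE_0065	GENE_0465	GENE_0100	GENE_0241	GENE_0332	GENE_0393	GENE_0257	GENE_0247	GENE_0329	GENE_0284	GENE_0264	GENE_0243	GENE_0151	GENE_0523	GENE_0308
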