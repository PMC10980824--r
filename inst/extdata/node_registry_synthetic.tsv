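id	name	mni_x	mni_y	mni_z	source
N001	Precentral_L	NA	NA	NA	AAL
N002	Precentral_R	NA	NA	NA	AAL
N003	Frontal_Sup_L	NA	NA	NA	AAL
N004	Frontal_Sup_R	NA	NA	NA	AAL
N005	Frontal_Sup_Orb_L	NA	NA	NA	AAL
N006	Frontal_Sup_Orb_R	NA	NA	NA	AAL
N007	Frontal_Mid_L	NA	NA	NA	AAL
N008	Frontal_Mid_R	NA	NA	NA	AAL
N009	Frontal_Mid_Orb_L	NA	NA	NA	AAL
N010	Frontal_Mid_Orb_R	NA	NA	NA	AAL
N011	Frontal_Inf_Oper_L	NA	NA	NA	AAL
N012	Frontal_Inf_Oper_R	NA	NA	NA	AAL
N013	Frontal_Inf_Tri_L	NA	NA	NA	AAL
N014	Frontal_Inf_Tri_R	NA	NA	NA	AAL
N015	Frontal_Inf_Orb_L	NA	NA	NA	AAL
N016	Frontal_Inf_Orb_R	NA	NA	NA	AAL
N017	Rolandic_Oper_L	NA	NA	NA	AAL
N018	Rolandic_Oper_R	NA	NA	NA	AAL
N019	Supp_Motor_Area_L	NA	NA	NA	AAL
N020	Supp_Motor_Area_R	NA	NA	NA	AAL
N021	Olfactory_L	NA	NA	NA	AAL
N022	Olfactory_R	NA	NA	NA	AAL
N023	Frontal_Sup_Medial_L	NA	NA	NA	AAL
N024	Frontal_Sup_Medial_R	NA	NA	NA	AAL
N025	Frontal_Med_Orb_L	NA	NA	NA	AAL
N026	Frontal_Med_Orb_R	NA	NA	NA	AAL
N027	Rectus_L	NA	NA	NA	AAL
N028	Rectus_R	NA	NA	NA	AAL
N029	Insula_L	NA	NA	NA	AAL
N030	Insula_R	NA	NA	NA	AAL
N031	Cingulum_Ant_L	NA	NA	NA	AAL
N032	Cingulum_Ant_R	NA	NA	NA	AAL
N033	Cingulum_Mid_L	NA	NA	NA	AAL
N034	Cingulum_Mid_R	NA	NA	NA	AAL
N035	Cingulum_Post_L	NA	NA	NA	AAL
N036	Cingulum_Post_R	NA	NA	NA	AAL
N037	Hippocampus_L	NA	NA	NA	AAL
N038	Hippocampus_R	NA	NA	NA	AAL
N039	ParaHippocampal_L	NA	NA	NA	AAL
N040	ParaHippocampal_R	NA	NA	NA	AAL
N041	Amygdala_L	NA	NA	NA	AAL
N042	Amygdala_R	NA	NA	NA	AAL
N043	Calcarine_L	NA	NA	NA	AAL
N044	Calcarine_R	NA	NA	NA	AAL
N045	Cuneus_L	NA	NA	NA	AAL
N046	Cuneus_R	NA	NA	NA	AAL
N047	Lingual_L	NA	NA	NA	AAL
N048	Lingual_R	NA	NA	NA	AAL
N049	Occipital_Sup_L	NA	NA	NA	AAL
N050	Occipital_Sup_R	NA	NA	NA	AAL
N051	Occipital_Mid_L	NA	NA	NA	AAL
N052	Occipital_Mid_R	NA	NA	NA	AAL
N053	Occipital_Inf_L	NA	NA	NA	AAL
N054	Occipital_Inf_R	NA	NA	NA	AAL
N055	Fusiform_L	NA	NA	NA	AAL
N056	Fusiform_R	NA	NA	NA	AAL
N057	Postcentral_L	NA	NA	NA	AAL
N058	Postcentral_R	NA	NA	NA	AAL
N059	Parietal_Sup_L	NA	NA	NA	AAL
N060	Parietal_Sup_R	NA	NA	NA	AAL
N061	Parietal_Inf_L	NA	NA	NA	AAL
N062	Parietal_Inf_R	NA	NA	NA	AAL
N063	SupraMarginal_L	NA	NA	NA	AAL
N064	SupraMarginal_R	NA	NA	NA	AAL
N065	Angular_L	NA	NA	NA	AAL
N066	Angular_R	NA	NA	NA	AAL
N067	Precuneus_L	NA	NA	NA	AAL
N068	Precuneus_R	NA	NA	NA	AAL
N069	Paracentral_Lobule_L	NA	NA	NA	AAL
N070	Paracentral_Lobule_R	NA	NA	NA	AAL
N071	Caudate_L	NA	NA	NA	AAL
N072	Caudate_R	NA	NA	NA	AAL
N073	Putamen_L	NA	NA	NA	AAL
N074	Putamen_R	NA	NA	NA	AAL
N075	Pallidum_L	NA	NA	NA	AAL
N076	Pallidum_R	NA	NA	NA	AAL
N077	Thalamus_L	NA	NA	NA	AAL
N078	Thalamus_R	NA	NA	NA	AAL
N079	Heschl_L	NA	NA	NA	AAL
N080	Heschl_R	NA	NA	NA	AAL
N081	Temporal_Sup_L	NA	NA	NA	AAL
N082	Temporal_Sup_R	NA	NA	NA	AAL
N083	Temporal_Pole_Sup_L	NA	NA	NA	AAL
N084	Temporal_Pole_Sup_R	NA	NA	NA	AAL
N085	Temporal_Mid_L	NA	NA	NA	AAL
N086	Temporal_Mid_R	NA	NA	NA	AAL
N087	Temporal_Pole_Mid_L	NA	NA	NA	AAL
N088	Temporal_Pole_Mid_R	NA	NA	NA	AAL
N089	Temporal_Inf_L	NA	NA	NA	AAL
N090	Temporal_Inf_R	NA	NA	NA	AAL
N091	Cerebelum_Crus1_L	NA	NA	NA	AAL
N092	Cerebelum_Crus1_R	NA	NA	NA	AAL
N093	Cerebelum_Crus2_L	NA	NA	NA	AAL
N094	Cerebelum_Crus2_R	NA	NA	NA	AAL
N095	Cerebelum_3_L	NA	NA	NA	AAL
N096	Cerebelum_3_R	NA	NA	NA	AAL
N097	Cerebelum_4_5_L	NA	NA	NA	AAL
N098	Cerebelum_4_5_R	NA	NA	NA	AAL
N099	Cerebelum_6_L	NA	NA	NA	AAL
N100	Cerebelum_6_R	NA	NA	NA	AAL
N101	Cerebelum_7b_L	NA	NA	NA	AAL
N102	Cerebelum_7b_R	NA	NA	NA	AAL
N103	Cerebelum_8_L	NA	NA	NA	AAL
N104	Cerebelum_8_R	NA	NA	NA	AAL
N105	Cerebelum_9_L	NA	NA	NA	AAL
N106	Cerebelum_9_R	NA	NA	NA	AAL
N107	Cerebelum_10_L	NA	NA	NA	AAL
N108	Cerebelum_10_R	NA	NA	NA	AAL
N109	Vermis_1_2	NA	NA	NA	AAL
N110	Vermis_3	NA	NA	NA	AAL
N111	Vermis_4_5	NA	NA	NA	AAL
N112	Vermis_6	NA	NA	NA	AAL
N113	Vermis_7	NA	NA	NA	AAL
N114	Vermis_8	NA	NA	NA	AAL
N115	Vermis_9	NA	NA	NA	AAL
N116	Vermis_10	NA	NA	NA	AAL
N117	Motor_Lit_M1_Hand_L	NA	NA	NA	literature
N118	Motor_Lit_M1_Hand_R	NA	NA	NA	literature
N119	Motor_Lit_PMd_L	NA	NA	NA	literature
N120	Motor_Lit_PMd_R	NA	NA	NA	literature
N121	Motor_Lit_SMA_proper	NA	NA	NA	literature
N122	Motor_Lit_preSMA	NA	NA	NA	literature
N123	Motor_Lit_Putamen_post_L	NA	NA	NA	literature
N124	Motor_Lit_Cerebellum_VI_R	NA	NA	NA	literature
N125	Motor_Lit_SPC_L	NA	NA	NA	literature
N126	Motor_Lit_DLPFC_L	NA	NA	NA	literature
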