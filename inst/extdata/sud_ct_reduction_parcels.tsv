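category	network_heading	hemisphere	name
common_aud_oud	Default mode network	L	DMNb_PrefrontalCortex_dorsal_4
common_aud_oud	Executive control network	L	ECNa_PrefrontalCortex_dorsal_1
common_aud_oud	Attention networks	R	SAL/VANa_FrontalMedial_2
common_aud_oud	Attention networks	R	SAL/VANb_PrefrontalCortex_lateral_1
common_aud_oud	Attention networks	R	SAL/VANb_Insula_2
common_aud_oud	Limbic network	R	Limbicb_OrbitofrontalCortex_4
common_aud_oud	Somatomotor network	L	SMNb_Aud_1
exclusive_aud	Default mode network	L	DMNa_PrefrontalCortex_medial_2
exclusive_aud	Default mode network	L	DMNa_PrefrontalCortex_dorsal_2
exclusive_aud	Default mode network	L	DMNb_PrefrontalCortex_dorsal_3
exclusive_aud	Default mode network	L	DMNb_PrefrontalCortex_dorsal_2
exclusive_aud	Default mode network	L	DMNb_PrefrontalCortex_dorsal_1
exclusive_aud	Default mode network	R	DMNa_PrefontalCortex_medial_3
exclusive_aud	Default mode network	R	DMNa_PrefontalCortex_dorsal_1
exclusive_aud	Default mode network	R	DMNb_PrefontalCortex_dorsal_1
exclusive_aud	Executive control network	L	ECNa_PrefrontalCortex_dorsal_1
exclusive_aud	Executive control network	L	ECNb_PrefrontalCortex_lateral_ventral_2
exclusive_aud	Executive control network	R	ECNa_PrefrontalCortex_dorsal_1
exclusive_aud	Executive control network	R	ECNa_PrefrontalCortex_lateral_1
exclusive_aud	Executive control network	R	ECNb_PrefrontalCortex_medial_posterior_1
exclusive_aud	Executive control network	R	ECNb_PrefrontalCortex_lateral_dorsal_3
exclusive_aud	Executive control network	R	ECNb_PrefrontalCortex_lateral_ventral_2
exclusive_aud	Executive control network	R	ECNb_PrefrontalCortex_lateral_dorsal_2
exclusive_aud	Attention networks	L	SAL/VANb_PrefrontalCortex_lateral_1
exclusive_aud	Attention networks	R	SAL/VANa_PrefrontalCortex_medial_1
exclusive_aud	Attention networks	R	SAL/VANb_PrefrontalCortex_lateral_ventral_1
exclusive_oud	Executive control network	R	ECNb_PrefrontalCortex_lateral_ventral_1
exclusive_oud	Executive control network	R	ECNb_IntraparietalLobe_1
exclusive_oud	Attention networks	R	SAL/VANa_ParsOpercularis_1
exclusive_oud	Attention networks	R	SAL/VANb_Insula_1
exclusive_oud	Attention networks	R	SAL/VANb_PrefrontalCortex_lateral_1
exclusive_oud	Attention networks	R	DANa_SuperiorParietalLobe_4
exclusive_oud	Temporoparietal network	R	Temporparietal_Region_4
exclusive_oud	Somatomotor network	R	SMNb_Auditory_2
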