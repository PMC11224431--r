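age_group	characteristic	category	n	group_total
all	total	total	8230	8230
ge65	total	total	6119	8230
lt65	total	total	2111	8230
lt60	total	total	989	8230
lt55	total	total	434	8230
lt50	total	total	189	8230
lt45	total	total	100	8230
ge65	sex	female	3036	6117
lt65	sex	female	1095	2109
ge65	histology	adenocarcinoma	3634	6119
lt65	histology	adenocarcinoma	1304	2111
lt45	histology	adenocarcinoma	69	100
ge65	histology	squamous	1464	6119
lt65	histology	squamous	379	2111
lt50	histology	squamous	14	189
lt45	histology	squamous	7	100
ge65	histology	other_nos	984	6119
lt65	histology	other_nos	401	2111
ge65	specimen_site	primary	4311	6119
lt65	specimen_site	primary	1316	2111
ge65	specimen_site	advanced	1147	6119
lt65	specimen_site	advanced	480	2111
ge65	specimen_site	metastatic	661	6119
lt65	specimen_site	metastatic	315	2111
lt50	specimen_site	metastatic	37	189
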