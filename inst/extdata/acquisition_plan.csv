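facility,condition,incubation_h,n_tilt_series,pixel_size_nm
ALBA,3h,3,21,11.5
ALBA,6h,6,13,11.5
ALBA,12h,12,20,11.5
ALBA,24h,24,7,11.5
ALBA,CTR,0,8,11.5
HZB-BESSYII,24h,24,24,15.56
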