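"area_nm2","sigma_mNm","sem_mNm"
42.4,0.229693175197839,0.963518540140917
43.8,3.98918480330244,1.33526439090056
45.2,10.291392939984,2.44386389795087
46.6,18.7686063416309,2.91701640353796
48,26.5616687583778,2.03474077783089
49.4,31.2391443979752,2.25110579390749
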