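"area_nm2","sigma_mNm","sem_mNm"
42.4,2.47182044514337,1.28655559633111
43.8,9.11112936940751,1.96062200358312
45.2,16.3511723896746,1.66028545280631
46.6,25.9005461400277,1.95372235999778
48,27.5559967999,2.1144128660209
49.4,41.3274569677154,1.14363156945495
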