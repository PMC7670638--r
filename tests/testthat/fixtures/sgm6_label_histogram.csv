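"label","n_voxels"
1,8720
2,368
3,368
4,352
5,352
6,368
7,368
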