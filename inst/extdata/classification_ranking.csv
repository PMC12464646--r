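option,rank1,rank2,rank3
"Traffic light (red, amber and green)",17,11,1
Levels (1-4),11,11,8
Only high-risk indicators,1,7,20
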