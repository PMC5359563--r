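code,name
1,FL
2,IFL
3,CL
4,O
5,CoL
6,W
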