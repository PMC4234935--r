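[species]
S(s1{free,bound,hidden}, s2{2,4,6,8,0}) = 1

[globals]
k = 1

[reactions]
step : S(s1{free}, s2{2}) -> S(succ(s1), succ(s2)) | MA : k

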