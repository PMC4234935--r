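[species]
Cdh1(p{0:maxP}) = 1
ClbM = 1

[globals]
maxP = 10
kp = 1
kd = 0.5
Cdh1T := SUM(Cdh1;p{1:maxP})

[reactions]
phos : Cdh1(p{0:maxP - 1}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : kp
dephos : Cdh1(p{1:maxP}) -> Cdh1(pred(p)) | MA : kd

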