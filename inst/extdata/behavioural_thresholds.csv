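id,20,25,30,35,40,45,50,55,60,65,70,75,80,85,90,95,100,105,110,115,120
F1,90,55,NaN,50,NaN,55,50,50,NaN,NaN,NaN,NaN,55,NaN,55,NaN,50,50,55,50,60
F2,85,60,55,55,55,50,55,55,55,55,55,NaN,60,55,60,55,55,55,55,55,55
F3,80,60,60,60,60,60,60,60,60,60,60,60,60,60,NaN,60,NaN,60,60,55,60
F4,75,65,65,55,65,65,65,65,65,65,65,65,65,65,65,65,70,NaN,60,65,NaN
F5,60,70,50,50,70,70,50,70,60,70,70,55,50,70,NaN,NaN,NaN,55,75,50,70
F6,75,75,55,50,50,60,NaN,NaN,60,55,80,75,NaN,50,60,NaN,60,NaN,60,70,50
F7,80,70,60,50,55,55,50,60,55,55,50,50,50,50,50,65,65,55,NaN,60,55
F8,85,55,55,55,50,50,NaN,NaN,55,60,NaN,50,NaN,NaN,55,50,70,65,50,NaN,NaN
F9,90,60,60,50,55,60,55,50,60,NaN,55,NaN,60,60,55,55,50,50,NaN,60,55
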