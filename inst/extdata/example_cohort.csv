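id,visit,DX,MMSE,DigitSpanF,FragLetters,ACancelTime
s01,0,HC,30,12,19,28
s01,1,HC,29,12,20,30
s02,0,HC,29,11,20,26
s03,0,HC,30,12,18,31
s04,0,HC,28,10,19,29
s05,0,HC,30,11,20,27
s06,0,AD,24,9,12,55
s06,1,AD,21,8,10,70
s07,0,AD,19,7,8,88
s08,0,AD,22,8,14,61
s08,1,AD,18,6,,95
s09,0,AD,15,5,6,120
s10,0,AD,25,9,15,48
s11,0,AD,20,7,9,90
s12,0,AD,17,6,7,104
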