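label,L,a,b
white,96,0,2
light pink,85,17,5
pink,75,35,5
red,53,70,50
dark red,35,55,35
yellow,90,-5,85
orange,70,35,75
purple,45,50,-40
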