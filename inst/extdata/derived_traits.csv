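trait_id,family,formula
A1,branching,GP1
A2,branching,GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22
TRIA,branching,GP23+GP24+GP25+GP27+GP30+GP31+GP32
TETRA,branching,GP26+GP28+GP29+GP33+GP34+GP35+GP36+GP37+GP38+GP39
LB,degree of branching,GP1+GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22
HB,degree of branching,GP23+GP24+GP25+GP26+GP27+GP28+GP29+GP30+GP31+GP32+GP33+GP34+GP35+GP36+GP37+GP38+GP39
G0,galactosylation,GP1+GP2+GP3
G1,galactosylation,GP4+GP5+GP6+GP7
G2,galactosylation,GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22
G3,galactosylation,GP30+GP31+GP32
G4,galactosylation,GP34+GP36+GP38+GP39
A2G,galactosylation,100*(GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22)/(GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22)
S1,sialylation,GP13+GP14+GP15+GP16+GP17
S2,sialylation,GP18+GP19+GP20+GP21+GP22
S3,sialylation,GP30+GP31+GP32+GP33+GP35
S4,sialylation,GP36+GP37+GP38+GP39
A2S0,sialylation of biantennary,100*(GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12)/(GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22)
BAMS,sialylation of biantennary,100*(GP13+GP14+GP15+GP16+GP17)/(GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22)
BADS,sialylation of biantennary,100*(GP18+GP19+GP20+GP21+GP22)/(GP2+GP3+GP4+GP5+GP6+GP7+GP8+GP9+GP10+GP11+GP12+GP13+GP14+GP15+GP16+GP17+GP18+GP19+GP20+GP21+GP22)
CF,fucose position,GP1+GP3+GP4+GP5+GP6+GP10+GP12+GP16+GP17+GP20+GP22
AF,fucose position,GP24+GP27+GP29+GP31+GP33+GP35+GP37+GP39
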