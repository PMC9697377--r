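class,detector,recall,ap
LLD,FPN,83.3,81.8
OF,FPN,60.6,56.4
AY,FPN,88.2,74.5
SLF,FPN,56.0,49.7
DP,FPN,48.8,45.5
HA,FPN,85.9,79.4
LS,FPN,100,100
SEH,FPN,60.0,54.5
RP,FPN,61.1,48.9
SF,FPN,69.4,61.4
LLD,S-RPN,100,100
OF,S-RPN,67.6,59.1
AY,S-RPN,83.1,80.1
SLF,S-RPN,63.4,58.3
DP,S-RPN,46.0,44.6
HA,S-RPN,80.4,79.4
LS,S-RPN,100,100
SEH,S-RPN,58.8,53.6
RP,S-RPN,68.4,58.5
SF,S-RPN,68.6,62.1
LLD,Cascade R-CNN,100,100
OF,Cascade R-CNN,59.2,51.6
AY,Cascade R-CNN,88.9,81.8
SLF,Cascade R-CNN,55.4,49.6
DP,Cascade R-CNN,46.3,44.7
HA,Cascade R-CNN,81.5,78.5
LS,Cascade R-CNN,100,100
SEH,Cascade R-CNN,58.8,52.9
RP,Cascade R-CNN,62.0,51.4
SF,Cascade R-CNN,67.0,62.1
LLD,AMFFP,100,100
OF,AMFFP,69.0,60.0
AY,AMFFP,83.3,81.8
SLF,AMFFP,64.1,58.1
DP,AMFFP,46.3,44.0
HA,AMFFP,82.6,79.6
LS,AMFFP,100,100
SEH,AMFFP,58.8,53.6
RP,AMFFP,70.1,61.7
SF,AMFFP,69.1,62.5
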