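>nc01
TCCactaaccaatatAAC
>nc02
TAActaacttaactcAAC
>nc03
CACaatctaactattAAC
>nc04
AAAtctataataaccacCAC
>nc05
CACaactattaaataccAAC
>nc06
TACcatacaataactttAAC
>nc07
CTAatattataaccatcAAC
>nc08
TACtcaaatataacaccAAC
>nc09
CAACcaacaatactttAAAC
>nc10
CAAAtcatccatctatAAAC
>nc11
CAAActtatatctttcAAAC
>nc12
CTAAatccttaatatcAAAC
>nc13
CcAAAtcttataataACtAC
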