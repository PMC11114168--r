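id,MA1,MA2,VA1,VA2,VA3,VA4
Sub01,NA,NA,NA,NA,NA,NA
Sub02,NA,0.07,NA,NA,NA,NA
Sub03,NA,NA,NA,NA,NA,NA
Sub04,NA,NA,NA,NA,NA,NA
Sub05,NA,NA,NA,NA,NA,NA
Sub06,NA,NA,NA,NA,NA,NA
Sub07,NA,NA,NA,NA,NA,NA
Sub08,NA,NA,NA,NA,NA,NA
Sub09,0.19,NA,NA,NA,NA,NA
Sub10,NA,0.14,NA,0.58,NA,NA
Sub11,NA,NA,NA,NA,NA,NA
Sub12,NA,NA,NA,NA,0.49,NA
Sub13,NA,NA,NA,NA,NA,NA
Sub14,NA,NA,NA,NA,NA,NA
Sub15,NA,NA,NA,NA,0.33,0.28
Sub16,NA,NA,NA,NA,NA,NA
Sub17,NA,NA,NA,NA,NA,0.10
Sub18,NA,NA,NA,NA,NA,NA
Sub19,NA,NA,NA,NA,NA,NA
Sub20,NA,NA,NA,NA,NA,NA
Sub22,NA,NA,NA,NA,NA,0.09
Sub23,NA,NA,NA,NA,0.24,NA
Sub24,NA,NA,NA,NA,NA,NA
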