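name,met
walking slow,2.8
walking brisk,4.3
jogging,7.0
running,9.8
cycling leisure,5.8
swimming,6.0
gardening,3.8
housework,3.3
cooking,2.0
shopping,2.3
stair climbing,4.0
yoga,2.5
dancing,4.5
strength training,5.0
stretching,2.3
table tennis,4.0
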