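51,49,38
57,79,119
28,84,105
0,2,6
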