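component,class,obs,precision,recall,f1
floor,unimproved,108931,0.73,0.74,0.73
floor,improved,149541,0.81,0.80,0.80
wall,unimproved,81621,0.71,0.59,0.65
wall,improved,166800,0.82,0.88,0.85
roof,unimproved,46272,0.76,0.38,0.50
roof,improved,188752,0.86,0.97,0.91
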