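# Candidate-table genes with a published report establishing them as p53
# targets (one symbol per line); the remaining ten table genes are novel.
ACER2
BTG2
EDA2R
GDF15
GLS2
SPATA18
TNFRSF10C
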