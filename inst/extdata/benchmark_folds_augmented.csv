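fold,type,precision,recall,f1,accuracy
1,Benign,92.945,95.733,94.319,94.233
1,Malignant,95.601,92.733,94.146,94.233
2,Benign,95.652,96.8,96.223,96.2
2,Malignant,96.761,95.6,96.177,96.2
3,Benign,95.976,97,96.485,96.467
3,Malignant,96.968,95.933,96.448,96.467
4,Benign,97.642,96.6,97.118,97.133
4,Malignant,96.636,97.667,97.149,97.133
5,Benign,97.732,97.667,97.699,97.7
5,Malignant,97.668,97.733,97.701,97.7
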