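fold,type,precision,recall,f1,accuracy
1,Benign,88.924,76,81.955,83.267
1,Malignant,79.045,90.533,84.400,83.267
2,Benign,86.898,86.667,86.782,86.8
2,Malignant,86.702,86.933,86.818,86.8
3,Benign,91.265,80.8,85.714,86.533
3,Malignant,82.775,92.267,87.264,86.533
4,Benign,90.054,89.333,89.692,89.733
4,Malignant,89.418,90.133,89.774,89.733
5,Benign,85.185,92,88.462,88
5,Malignant,91.304,84,87.500,88
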