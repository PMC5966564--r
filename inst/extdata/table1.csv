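subject,accuracy_training,accuracy_testing,precision,recall,f1
1,90.00,100.00,100.00,100.00,100.00
2,100.00,60.00,66.67,40.00,50.00
3,100.00,70.00,100.00,40.00,57.14
4,100.00,100.00,100.00,100.00,100.00
5,100.00,70.00,75.00,60.00,66.67
6,100.00,80.00,100.00,60.00,75.00
7,100.00,90.00,100.00,80.00,88.89
8,100.00,80.00,80.00,80.00,80.00
9,100.00,90.00,100.00,80.00,88.89
10,80.00,70.00,100.00,40.00,57.14
11,70.00,50.00,50.00,100.00,66.67
12,90.00,60.00,55.56,100.00,71.43
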