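run,att_s,train_accuracy,test_accuracy,TNS,FPS,FNS,TPS,sensitivity,specificity
1,0.1438,100,92.8,91,6,3,25,89.5,94
2,0.144,100,92,90,7,3,25,89.3,92.8
3,0.1532,100,93.6,93,4,4,24,86.7,95.9
4,0.1436,100,92.8,93,5,4,23,83.8,94.7
5,0.1314,100,94.4,93,5,2,25,92.5,94.9
6,0.1312,100,93.6,92,5,3,25,89.8,94.8
7,0.1374,100,94.4,94,4,3,24,91.3,96.3
8,0.1594,100,91.2,92,5,6,22,78.6,94.7
9,0.153,100,94.4,95,2,5,23,84.5,97.8
10,0.1346,100,92,90,7,3,25,91.4,92.3
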