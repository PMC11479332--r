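participant,sex,height_cm,weight_kg
1,F,170.0,92.0
2,M,172.7,75.2
3,M,181.0,88.7
4,M,181.0,99.8
5,F,157.5,87.8
6,F,157.5,50.3
7,M,175.0,73.8
8,M,165.0,65.5
10,M,198.0,120.3
11,F,161.3,62.6
12,F,165.1,49.2
13,F,175.0,57.4
14,F,175.0,60.8
15,F,170.0,63.7
17,M,188.0,107.6
18,M,179.0,81.8
19,M,185.4,78.0
20,M,183.0,88.5
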