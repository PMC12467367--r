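person_id,age,gender,measure_a,se_a,measure_b,se_b
1-CVA-L,82,M,-0.79,0.29,-0.69,0.29
2-CVA-L,73,F,-2.97,0.40,-2.94,0.39
3-CVA-L,72,M,-2.27,0.35,-2.29,0.34
4-CVA-L,75,M,-2.53,0.37,-2.53,0.36
5-CVA-R,22,M,-3.50,0.45,-3.45,0.44
6-CVA-R,62,M,-2.40,0.36,-2.29,0.34
7-CVA-R,84,F,-3.31,0.43,-3.26,0.42
8-CVA-L,83,M,-1.32,0.31,-1.22,0.30
9-CVA-R,73,M,-1.51,0.31,-1.56,0.31
10-CVA-L,73,F,-1.61,0.32,-1.51,0.31
11-CVA-R,70,M,-3.72,0.48,-3.66,0.47
12-CVA-R,80,F,-0.53,0.29,-0.55,0.29
13-CVA-R,71,F,-3.96,0.51,-3.89,0.50
14-CVA-R,75,M,-2.04,0.34,-2.06,0.33
15-CVA-R,72,M,-2.15,0.34,-2.06,0.33
16-CVA-R,61,M,-4.04,0.75,-4.17,0.55
17-CVA-R,70,M,-3.13,0.41,-3.10,0.40
18-CVA-R,70,M,-2.81,0.39,-2.79,0.38
19-CVA-R,54,M,-1.82,0.33,-1.57,0.32
20-CVA-L,60,F,-2.53,0.37,-2.53,0.36
21-CVA-L,78,F,-1.51,0.31,-1.56,0.31
22-CVA-L,73,M,-1.61,0.32,-1.56,0.31
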