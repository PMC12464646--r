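row,round,n,median,mean,pct_1_4,pct_5_7,pct_6_7
1,1,32,7,6.6,0.0,100.0,96.9
1,2,30,7,6.6,0.0,100.0,100.0
2,1,32,7,6.5,3.1,96.9,90.6
2,2,30,7,6.6,0.0,100.0,96.7
3,1,32,6,6.2,3.1,96.9,81.3
3,2,30,6,6.3,0.0,100.0,93.3
4,1,32,6,6.1,6.3,93.8,78.1
4,2,30,6,6.2,0.0,100.0,90.0
5,1,32,6,6.3,0.0,100.0,81.3
5,2,30,6,6.4,0.0,100.0,90.0
6,1,32,7,6.4,3.1,96.9,90.6
6,2,30,7,6.4,0.0,100.0,86.7
7,1,32,7,6.6,3.1,96.9,96.9
7,2,30,7,6.6,3.3,96.7,96.7
8,1,32,6.5,6.3,3.1,96.9,87.5
8,2,30,6,6.3,3.3,96.7,93.3
9,1,32,6,6.0,6.3,93.8,81.3
9,2,30,6,6.2,3.3,96.7,93.3
10,1,32,6,5.8,18.8,81.3,75.0
10,2,30,6,5.9,3.3,96.7,76.7
11,1,32,6,5.6,12.5,87.5,62.5
11,2,30,6,5.7,3.3,96.7,70.0
12,1,32,6,6.0,6.3,93.8,68.8
12,2,30,6,5.8,6.7,93.3,63.3
13,1,32,6,5.1,25.0,75.0,53.1
13,2,30,6,5.6,10.0,90.0,76.7
14,1,32,5,5.2,25.0,75.0,46.9
14,2,30,5,5.2,16.7,83.3,46.7
15,1,32,5,5.1,28.1,71.9,31.3
15,2,30,5,5.0,16.7,83.3,20.0
16,1,32,6,5.3,25.0,75.0,53.1
16,2,30,6,5.4,20.0,80.0,56.7
17,1,32,5,5.0,28.1,71.9,40.6
17,2,30,5,5.0,23.3,76.7,30.0
18,1,32,5,4.5,43.8,56.3,31.3
18,2,30,5,4.8,26.7,73.3,23.3
19,1,32,5,4.6,43.8,56.3,37.5
19,2,30,5,4.5,33.3,66.7,30.0
20,1,32,5,4.6,43.8,56.3,37.5
20,2,30,5,4.7,33.3,66.7,26.7
21,1,32,5,4.8,40.6,59.4,40.6
21,2,30,5,4.6,36.7,63.3,26.7
22,1,32,5,4.7,40.6,59.4,34.4
22,2,30,5,4.6,36.7,63.3,26.7
23,1,32,5,4.7,37.5,62.5,34.4
23,2,30,5,4.4,40.0,60.0,23.3
24,1,32,5,4.3,46.9,53.1,25.0
24,2,30,5,4.5,40.0,60.0,10.0
25,1,,,,,,
25,2,30,5,4.3,43.3,56.7,20.0
26,1,32,5,4.3,43.8,56.3,21.9
26,2,30,5,4.4,43.3,56.7,13.3
27,1,32,5,4.2,46.9,53.1,31.3
27,2,30,4,3.9,56.7,43.3,13.3
28,1,32,4,4.2,53.1,46.9,18.8
28,2,30,4,4.1,60.0,40.0,6.7
29,1,32,4,3.9,65.6,34.4,12.5
29,2,30,4,3.9,63.3,36.7,10.0
30,1,32,3,3.3,75.0,25.0,9.4
30,2,30,3,3.2,83.3,16.7,10.0
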