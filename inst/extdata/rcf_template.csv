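id,kind,x1,y1,x2,y2,r,unit,structure
1,segment,-40,28,40,28,,2,base_rectangle
2,segment,40,28,40,-28,,2,base_rectangle
3,segment,40,-28,-40,-28,,2,base_rectangle
4,segment,-40,-28,-40,28,,2,base_rectangle
5,segment,-40,28,40,-28,,3,main_substructure
6,segment,-40,-28,40,28,,3,main_substructure
7,segment,-40,0,40,0,,4,main_substructure
8,segment,0,28,0,-28,,5,main_substructure
9,segment,-32,36,-32,48,,1,outer_configuration
10,segment,-38,42,-26,42,,1,outer_configuration
11,segment,-32,28,-32,36,,1,outer_configuration
12,segment,-40,24.5,-35,24.5,,8,inner_detail
13,segment,-40,21,-30,21,,8,inner_detail
14,segment,-40,17.5,-25,17.5,,8,inner_detail
15,segment,-40,14,-20,14,,8,inner_detail
16,segment,12,28,20,36,,9,outer_configuration
17,segment,20,36,28,28,,9,outer_configuration
18,segment,20,28,20,20,,10,inner_detail
19,segment,-30,-4,-10,-4,,6,inner_detail
20,segment,-10,-4,-10,-24,,6,inner_detail
21,segment,-10,-24,-30,-24,,6,inner_detail
22,segment,-30,-24,-30,-4,,6,inner_detail
23,segment,-30,-4,-10,-24,,6,inner_detail
24,segment,-30,-24,-10,-4,,6,inner_detail
25,point,28.5,17.5,,,,11,inner_detail
26,point,31.5,17.5,,,,11,inner_detail
27,point,30,14.5,,,,11,inner_detail
28,circle,30,16,,,4,11,inner_detail
29,segment,-26,-4.5,-14,-4.5,,7,inner_detail
30,segment,5.7061508,-8.87692759999999,10.2938492,-2.32307239999999,,12,inner_detail
31,segment,11.7061508,-13.0769276,16.2938492,-6.5230724,,12,inner_detail
32,segment,17.7061508,-17.2769276,22.2938492,-10.7230724,,12,inner_detail
33,segment,23.7061508,-21.4769276,28.2938492,-14.9230724,,12,inner_detail
34,segment,29.7061508,-25.6769276,34.2938492,-19.1230724,,12,inner_detail
35,segment,40,28,56,0,,13,outer_configuration
36,segment,56,0,40,-28,,13,outer_configuration
37,segment,56,0,62,6,,14,outer_configuration
38,segment,62,6,68,0,,14,outer_configuration
39,segment,68,0,62,-6,,14,outer_configuration
40,segment,62,-6,56,0,,14,outer_configuration
41,segment,48,14,48,-14,,15,inner_detail
42,segment,40,0,56,0,,16,inner_detail
43,segment,-12,-28,-12,-36,,17,outer_configuration
44,segment,-12,-36,-12,-44,,17,outer_configuration
45,segment,-18,-40,-6,-40,,17,outer_configuration
46,segment,-40,-14,-54,-14,,18,outer_configuration
47,segment,-54,-14,-54,-28,,18,outer_configuration
48,segment,-54,-28,-40,-28,,18,outer_configuration
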