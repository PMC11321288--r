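cluster,n_images,n_patients,ratio
1,310,196,1.6
2,262,173,1.5
3,400,166,2.4
4,370,174,2.1
5,234,156,1.5
6,249,102,2.4
7,166,114,1.5
8,166,103,1.6
9,198,69,2.9
10,197,121,1.6
11,395,170,2.3
12,268,110,2.4
13,205,126,1.6
14,233,69,3.4
15,435,174,2.5
16,326,135,2.4
17,187,55,3.4
18,152,75,2.0
19,226,148,1.5
20,123,73,1.7
21,218,133,1.6
22,155,82,1.9
23,303,114,2.7
24,396,139,2.8
25,136,93,1.5
26,233,75,3.1
27,152,46,3.3
28,206,88,2.3
29,211,67,3.1
30,235,55,4.3
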