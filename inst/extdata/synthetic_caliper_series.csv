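"day","diameter_mm","mouse"
3,11.3,1
6,11.1,1
9,13.28,1
12,14.56,1
15,14.93,1
18,16.91,1
21,18.33,1
24,18.61,1
27,20.29,1
3,10.26,2
6,11.34,2
9,12.76,2
12,13.82,2
15,15.95,2
18,15.96,2
21,18.33,2
24,18.97,2
27,20.48,2
3,10.26,3
6,11.41,3
9,12.72,3
12,14.01,3
15,16,3
18,16.08,3
21,17.65,3
24,18.65,3
27,21.08,3
3,10.47,4
6,11.55,4
9,12.46,4
12,14.24,4
15,15.67,4
18,16.64,4
21,18.13,4
24,19.37,4
27,20.19,4
3,9.95,5
6,11.09,5
9,11.96,5
12,13.15,5
15,14.72,5
18,16.1,5
21,17.62,5
24,19.49,5
27,20.85,5
3,10.5,6
6,11.29,6
9,12.96,6
12,13.92,6
15,15.06,6
18,16.37,6
21,17.61,6
24,18.86,6
27,20.68,6
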