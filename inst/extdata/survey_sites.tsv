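site_id	region	n	lat	lon
1	North	6	4	-53
2	North	2	1	-70
3	North	2	-0.5	-63
4	Andean	6	-1.5	-77.5
5	West	2	-12	-70.5
6	Andean	13	-8	-74.5
7	West	3	-3.5	-70
8	North	3	7.5	-67
9	South	2	-14.5	-62.5
10	West	1	5	-76.5
11	South	1	-2.5	-49.5
12	South	4	-25.5	-60.5
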