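chrom	pos	ref	alt
2	1042739	C	G
2	5716789	T	G
2	6282397	T	G
2	7143884	A	T
2	7422177	G	C
2	8569618	C	G
3	6299108	G	T
4	2161151	C	G
4	4319095	C	T
4	5079198	T	C
4	5769305	T	C
5	8026447	C	T
5	8729577	C	T
6	1638187	C	T
6	4892912	C	A
7	4478388	G	C
7	8192504	C	T
9	3920192	C	T
9	4862077	A	G
9	4901614	A	T
9	8385315	G	C
11	5259597	A	G
12	3165159	G	A
12	3386342	C	T
12	7682172	T	G
12	8975978	C	G
13	3031742	G	A
13	3765077	T	C
13	4443485	G	T
14	2825435	A	T
14	4875839	C	T
14	4927860	G	T
14	4973139	C	G
14	5429195	C	T
14	6725739	T	G
15	3310516	A	G
15	5858492	G	T
15	7591336	C	A
16	3491891	T	C
17	4129370	C	G
17	4733066	C	T
17	7615918	C	A
20	8157787	T	G
20	8207261	C	G
21	4173249	A	C
21	5345800	A	T
21	6362734	T	A
22	3202533	G	T
22	7263024	C	A
22	8135292	T	C
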