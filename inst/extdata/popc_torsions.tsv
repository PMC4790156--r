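index	atom1	atom2	atom3	atom4
1	C12	N	C11	C15
2	N	C11	C15	O1
3	C11	C15	O1	P1
4	C15	O1	P1	O2
5	O1	P1	O2	C1
6	P1	O2	C1	C2
7	O2	C1	C2	O21
8	C1	C2	O21	C21
9	C2	O21	C21	C22
10	O2	C1	C2	C3
11	C1	C2	C3	O31
12	C2	C3	O31	C31
13	C3	O31	C31	C32
14	O21	C21	C22	C23
15	C21	C22	C23	C24
16	C22	C23	C24	C25
17	C23	C24	C25	C26
18	C24	C25	C26	C27
19	C25	C26	C27	C28
20	C26	C27	C28	C29
21	C27	C28	C29	C210
22	C28	C29	C210	C211
23	C29	C210	C211	C212
24	C210	C211	C212	C213
25	C211	C212	C213	C214
26	C212	C213	C214	C215
27	C213	C214	C215	C216
28	C214	C215	C216	C217
29	C215	C216	C217	C218
30	O31	C31	C32	C33
31	C31	C32	C33	C34
32	C32	C33	C34	C35
33	C33	C34	C35	C36
34	C34	C35	C36	C37
35	C35	C36	C37	C38
36	C36	C37	C38	C39
37	C37	C38	C39	C310
38	C38	C39	C310	C311
39	C39	C310	C311	C312
40	C310	C311	C312	C313
41	C311	C312	C313	C314
42	C312	C313	C314	C315
43	C313	C314	C315	C316
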