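rs11206510	rs82070370	rs72090410	rs20178532	rs37905302	rs76657401	rs98141647	rs32572282	rs82560098	rs42458888
1	0.218	0.189	0.178	0.202	0.189	0.143	0.184	0.219	0.227
0.218	1	0.257	0.233	0.279	0.238	0.226	0.283	0.358	0.322
0.189	0.257	1	0.278	0.16	0.161	0.085	0.313	0.234	0.205
0.178	0.233	0.278	1	0.121	0.137	0.038	0.314	0.187	0.165
0.202	0.279	0.16	0.121	1	0.299	0.306	0.119	0.341	0.369
0.189	0.238	0.161	0.137	0.299	1	0.227	0.104	0.249	0.309
0.143	0.226	0.085	0.038	0.306	0.227	1	0.073	0.335	0.32
0.184	0.283	0.313	0.314	0.119	0.104	0.073	1	0.291	0.184
0.219	0.358	0.234	0.187	0.341	0.249	0.335	0.291	1	0.391
0.227	0.322	0.205	0.165	0.369	0.309	0.32	0.184	0.391	1
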