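s01	A
s02	A
s03	A
s04	A
s05	A
s06	A
s07	A
s08	A
s09	A
s10	A
s11	A
s12	A
s13	A
s14	A
s15	A
s16	A
s17	A
s18	A
s19	A
s20	A
s21	A
s22	A
s23	A
s24	A
s25	A
s26	A
s27	A
s28	A
s29	A
s30	A
s31	B
s32	B
s33	B
s34	B
s35	B
s36	B
s37	B
s38	B
s39	B
s40	B
s41	B
s42	B
s43	B
s44	B
s45	B
s46	B
s47	B
s48	B
s49	B
s50	B
s51	B
s52	B
s53	B
s54	B
s55	B
s56	B
s57	B
s58	B
s59	B
s60	B
s61	B
s62	B
s63	B
s64	B
s65	B
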