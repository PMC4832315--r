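variant	beta_exposure	se_exposure	beta_outcome	se_outcome	eaf	n_exposure	n_outcome
rs11206510	0.0752	0.0036	0.0611	0.0325	0.65	170000	86995
rs82070370	0.0686	0.0039	0.0688	0.0233	0.698	170000	86995
rs72090410	0.0665	0.0041	0.024	0.0244	0.813	170000	86995
rs20178532	0.0616	0.0055	0.0455	0.0265	0.781	170000	86995
rs37905302	0.0569	0.005	0.0421	0.0344	0.746	170000	86995
rs76657401	0.0491	0.0036	0.0515	0.031	0.946	170000	86995
rs98141647	0.0378	0.0033	0.0239	0.0332	0.702	170000	86995
rs32572282	0.0345	0.0051	0.0386	0.0185	0.893	170000	86995
rs82560098	0.0323	0.0059	0.0572	0.0345	0.713	170000	86995
rs42458888	0.0298	0.0049	0.0356	0.0184	0.565	170000	86995
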