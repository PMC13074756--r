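bin_center_nm,side,kd,ks,n_exp,tau
445,adaxial,0.033430602254041306,0.028163410787682072,15,0.042019496447621936
455,adaxial,0.03221534719652473,0.029782950118107058,15,0.04208701470700189
465,adaxial,0.03233522932465033,0.029782950118457496,15,0.042338125750859074
475,adaxial,0.034047281940664774,0.028163410791784298,15,0.04314396369377801
485,adaxial,0.037647816945886,0.025472873885206557,15,0.04536972644086498
495,adaxial,0.04407372502884715,0.022510604959937102,15,0.05064222282642496
505,adaxial,0.055252570756240946,0.019948883732991377,15,0.06129766147557869
515,adaxial,0.07325120004194398,0.018113699568848573,15,0.07951736404873307
525,adaxial,0.0978655618190983,0.01699852396525696,15,0.10550506451115797
535,adaxial,0.12419805723256695,0.016416668156516136,15,0.13559072610223083
545,adaxial,0.14326661291945972,0.016155172410098877,15,0.16208967937896748
555,adaxial,0.14688455992997873,0.016057847302550315,15,0.17616121287673947
565,adaxial,0.13342950418193655,0.016042647078268545,15,0.17249585557895186
575,adaxial,0.1091167074956421,0.01609109505374805,15,0.15251342642630303
585,adaxial,0.08349292571040906,0.016238637203531622,15,0.1234859166934278
595,adaxial,0.06351702817755636,0.01657069167468667,15,0.09431213485381114
605,adaxial,0.05106514326921778,0.01720784684096241,15,0.07124110306294541
615,adaxial,0.044412020228038196,0.01825650782978695,15,0.05623590991302788
625,adaxial,0.040963612080678766,0.019720346075678005,15,0.048050113953503816
635,adaxial,0.03894451139937949,0.021413070837442948,15,0.04428874657980037
645,adaxial,0.03771157552655637,0.02295052045728561,15,0.04291086844334209
655,adaxial,0.037429791666934456,0.02387597149671138,15,0.0427962296584215
665,adaxial,0.03885798172876431,0.02387597149609811,15,0.043855331013958616
675,adaxial,0.043869026002025586,0.022950520450106718,15,0.0474508755511583
685,adaxial,0.05756684124572279,0.021413070769294086,15,0.058103851161118485
695,adaxial,0.09244167027410623,0.019720345505072463,15,0.08736936154332164
705,adaxial,0.16693417320741577,0.018256503613550523,15,0.15495543975681794
715,adaxial,0.27484599327819187,0.017207819347647316,15,0.2636546839342549
725,adaxial,0.36596288729368565,0.016570533461582066,15,0.3664308413317246
735,adaxial,0.41373931293213795,0.01623783373108927,15,0.42487213562407283
445,abaxial,0.04865379140124776,0.016898046472609243,7,0.042019496447621936
455,abaxial,0.04793742496748132,0.017869770070864235,7,0.04208701470700189
465,abaxial,0.048071692951121486,0.017869770071074497,7,0.042338125750859074
475,abaxial,0.04934447265189909,0.016898046475070577,7,0.04314396369377801
485,abaxial,0.05230600130585435,0.015283724331123934,7,0.04536972644086498
495,abaxial,0.0583237745413433,0.013506362975962262,7,0.05064222282642496
505,abaxial,0.06982429118499311,0.011969330239794825,7,0.06129766147557869
515,abaxial,0.08925219112608287,0.010868219741309143,7,0.07951736404873307
525,abaxial,0.11637633825109478,0.010199114379154176,7,0.10550506451115797
535,abaxial,0.14563710327826615,0.009850000893909682,7,0.13559072610223083
545,abaxial,0.16688978731957277,0.009693103446059326,7,0.16208967937896748
555,abaxial,0.17090314401047393,0.009634708381530188,7,0.17616121287673947
565,abaxial,0.15582743054524145,0.009625588246961126,7,0.17249585557895186
575,abaxial,0.12861638481597987,0.00965465703224883,7,0.15251342642630303
585,abaxial,0.0999764839810968,0.009743182322118973,7,0.1234859166934278
595,abaxial,0.07773566565644148,0.009942415004812001,7,0.09431213485381114
605,abaxial,0.06404319840762772,0.010324708104577446,7,0.07124110306294541
615,abaxial,0.05700915999457513,0.010953904697872168,7,0.05623590991302788
625,abaxial,0.05372967936129925,0.011832207645406803,7,0.048050113953503816
635,abaxial,0.05214214007349403,0.012847842502465769,7,0.04428874657980037
645,abaxial,0.05137329219495423,0.013770312274371366,7,0.04291086844334209
655,abaxial,0.051426105258521704,0.014325582898026826,7,0.0427962296584215
665,abaxial,0.053025678127526996,0.014325582897658866,7,0.043855331013958616
675,abaxial,0.058269636724621925,0.01377031227006403,7,0.0474508755511583
685,abaxial,0.07299914947426928,0.01284784246157645,7,0.058103851161118485
695,abaxial,0.11138510431078678,0.011832207303043478,7,0.08736936154332164
705,abaxial,0.19423396965304476,0.010953902168130313,7,0.15495543975681794
715,abaxial,0.3146777394729189,0.01032469160858839,7,0.2636546839342549
725,abaxial,0.4164749648837623,0.00994232007694924,7,0.3664308413317246
735,abaxial,0.4698521178166669,0.00974270023865356,7,0.42487213562407283
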