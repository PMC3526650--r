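age,sex,n_csc,cyc_frac,mitosis_hours,expansion_exponent,apoptotic_frac,apoptosis_hours,halflife_years
0,male,24098.790782569,0.05,26,5,1.18640200775724e-05,4,18
10,male,44490.0752908966,0.05,26,5,2.2236351570616e-05,4,17
20,male,64881.3597992243,0.05,26,5,3.29294768211765e-05,4,16
30,male,85272.6443075519,0.05,26,5,4.39585117654718e-05,4,15
40,male,105663.92881588,0.05,26,5,5.53395371867127e-05,4,14
50,male,126055.213324207,0.05,26,5,6.70896769459398e-05,4,13
60,male,146446.497832535,0.05,26,5,7.92271839499766e-05,4,12
70,male,166837.782340862,0.05,26,5,9.17715347642045e-05,4,11
80,male,187229.06684919,0.05,26,5,0.000104743533901645,4,10
90,male,207620.351357518,0.05,26,5,0.000118165428962927,4,9
100,male,228011.635865845,0.05,26,5,0.000132061037967548,4,8
0,female,27806.2970568104,0.05,26,5,1.36892539356605e-05,4,18
10,female,55612.5941136208,0.05,26,5,2.54880043241276e-05,4,17
20,female,83418.8911704312,0.05,26,5,3.65474711693323e-05,4,16
30,female,111225.188227242,0.05,26,5,4.74217591048305e-05,4,15
40,female,139031.485284052,0.05,26,5,5.84035172030119e-05,4,14
50,female,166837.782340862,0.05,26,5,6.96530349356932e-05,4,13
60,female,194644.079397673,0.05,26,5,8.12556564643276e-05,4,12
70,female,222450.376454483,0.05,26,5,9.32504929736097e-05,4,11
80,female,250256.673511294,0.05,26,5,0.000105646384480388,4,10
90,female,278062.970568104,0.05,26,5,0.000118431713627263,4,9
100,female,305869.267624914,0.05,26,5,0.000131581022322515,4,8
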