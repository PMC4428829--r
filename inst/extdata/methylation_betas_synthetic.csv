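sample_id,group,cg0001,cg0002,cg0003
s01,control,0.4059,0.4436,0.2858
s02,control,0.2936,0.1931,0.3593
s03,control,0.2658,0.6294,0.4091
s04,control,0.7048,0.4141,0.0505
s05,control,0.348,0.3409,0.3747
s06,control,0.4404,0.3811,0.2516
s07,control,0.1813,0.3787,0.5202
s08,control,0.2496,0.5268,0.1906
s09,control,0.3251,0.3543,0.3976
s10,control,0.2029,0.6222,0.2422
s11,control,0.2954,0.4744,0.5088
s12,control,0.5549,0.1873,0.2654
s13,control,0.0878,0.3763,0.5643
s14,control,0.4018,0.1989,0.2421
s15,case,0.4243,0.4812,0.4541
s16,case,0.537,0.3986,0.627
s17,case,0.5776,0.4565,0.1601
s18,case,0.6581,0.3865,0.5844
s19,case,0.3626,0.364,0.7604
s20,case,0.2518,0.225,0.4614
s21,case,0.2252,0.461,0.8157
s22,case,0.2916,0.3841,0.3702
s23,case,0.6141,0.6494,0.3733
s24,case,0.4788,0.1333,0.3115
s25,case,0.7978,0.3364,0.5469
s26,case,0.7714,0.8054,0.8735
s27,case,0.5275,0.1239,0.4718
s28,case,0.2649,0.4851,0.652
s29,case,0.5027,0.1722,0.746
s30,case,0.5485,0.2769,0.5065
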