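# Molar extinction coefficients of human oxy- and deoxyhemoglobin,
# 1/(M*cm), compiled from standard published tabulations of hemoglobin
# optical absorption (Gratzer/Kollias compilation lineage).  Values are
# rounded to the nearest 1/(M*cm); intermediate wavelengths are obtained
# by linear interpolation.  Version 1, visible range 450-660 nm.
wavelength_nm	eps_hbo	eps_hbr
450	62816	68012
460	33209	45072
470	18882	33210
480	14550	26629
490	16684	23485
500	20932	20862
510	20035	25773
520	24202	31590
530	39036	39437
540	53236	46592
550	43016	52276
560	32613	53788
570	44496	45072
580	50104	37020
590	14400	26600
600	3200	14677
610	1506	9443
620	942	6510
630	610	5149
640	442	4345
650	368	3750
660	320	3227
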