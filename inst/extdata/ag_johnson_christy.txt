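# Optical constants of evaporated silver films.
# Source: P. B. Johnson and R. W. Christy, "Optical constants of the noble
# metals", Phys. Rev. B 6, 4370 (1972); visible/near-UV/near-IR subset,
# converted from photon energy to vacuum wavelength (nm).
# Columns: wavelength_nm  n  k
# wavelength_nm  n       k
248.47   0.932   1.323
255.11   1.04    1.296
261.57   1.11    1.258
268.36   1.18    1.212
276.13   1.27    1.163
284.37   1.36    1.118
292.42   1.32    1.003
300.93   1.32    0.902
310.74   1.13    0.616
320.37   0.81    0.392
331.51   0.17    0.829
342.50   0.14    1.142
354.24   0.10    1.419
367.91   0.07    1.657
381.49   0.05    1.864
397.39   0.05    2.070
413.28   0.05    2.275
430.50   0.04    2.462
450.85   0.04    2.657
471.42   0.05    2.869
495.94   0.05    3.093
520.94   0.05    3.324
548.60   0.06    3.586
582.08   0.05    3.858
616.84   0.06    4.152
659.49   0.05    4.483
704.46   0.04    4.838
756.00   0.03    5.242
821.09   0.04    5.727
892.69   0.04    6.312
984.00   0.04    6.992
1087.58  0.04    7.795
1215.53  0.09    8.828
1393.08  0.13   10.10
1610.18  0.15   11.85
1937.25  0.24   14.08
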