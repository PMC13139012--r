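##TITLE=synthetic kernel-granule demo spectrum
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=NANOMETERS
##YUNITS=ABSORBANCE
##FIRSTX=1000
##LASTX=1650
##NPOINTS=66
##XFACTOR=1
##YFACTOR=0.0001
##XYDATA=(X++(Y..Y))
1000 1450 1430 1412 1394 1376 1361 1346 1335 1328 1330 1344 1377 1437 1530 1658 1819 2000 2181 2337 2442 2476 2432 2318 2153 1963 1774 1608 1476 1386 1335 1322 1345 1402 1497 1631 1810 2036 2308 2620 2961 3313 3653 3958 4201 4361 4426 4390 4257 4042 3766 3454 3130 2817 2533 2289 2091 1938 1828 1754 1710 1689 1684 1692 1708 1729 1754
##END=
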