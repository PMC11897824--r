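wavelength_nm,eps_hbo2,eps_hb
450,1346.53,1500
451,1371.67,1500
452,1400.5,1500.01
453,1433.41,1500.01
454,1470.86,1500.01
455,1513.31,1500.02
456,1561.26,1500.03
457,1615.22,1500.04
458,1675.7,1500.06
459,1743.26,1500.09
460,1818.44,1500.13
461,1901.76,1500.19
462,1993.77,1500.28
463,2094.98,1500.4
464,2205.86,1500.56
465,2326.87,1500.79
466,2458.4,1501.11
467,2600.8,1501.55
468,2754.33,1502.14
469,2919.17,1502.94
470,3095.42,1504.01
471,3283.07,1505.44
472,3481.98,1507.34
473,3691.89,1509.85
474,3912.42,1513.12
475,4143.04,1517.37
476,4383.06,1522.87
477,4631.65,1529.91
478,4887.84,1538.88
479,5150.5,1550.23
480,5418.34,1564.5
481,5689.95,1582.31
482,5963.78,1604.4
483,6238.16,1631.59
484,6511.33,1664.84
485,6781.41,1705.23
486,7046.49,1753.94
487,7304.59,1812.27
488,7553.73,1881.65
489,7791.9,1963.57
490,8017.15,2059.6
491,8227.57,2171.38
492,8421.35,2300.52
493,8596.76,2448.64
494,8752.22,2617.25
495,8886.32,2807.73
496,8997.8,3021.28
497,9085.63,3258.83
498,9148.97,3520.98
499,9187.22,3807.93
500,9200.01,4119.46
501,9187.24,4454.8
502,9149.02,4812.66
503,9085.73,5191.13
504,8998,5587.73
505,8886.68,5999.35
506,8752.89,6422.32
507,8597.96,6852.46
508,8423.48,7285.11
509,8231.28,7715.28
510,8023.49,8137.75
511,7802.56,8547.24
512,7571.38,8938.55
513,7333.34,9306.74
514,7092.54,9647.4
515,6853.95,9956.73
516,6623.74,10231.87
517,6409.51,10470.99
518,6220.66,10673.55
519,6068.77,10840.38
520,5967.81,10973.9
521,5934.43,11078.14
522,5987.95,11158.83
523,6150.16,11223.4
524,6444.72,11280.95
525,6896.25,11342.13
526,7528.88,11418.97
527,8364.39,11524.72
528,9419.92,11673.52
529,10705.47,11880.1
530,12221.31,12159.4
531,13955.55,12526.09
532,15882.37,12994.18
533,17960.94,13576.44
534,20135.53,14283.96
535,22337,15125.56
536,24485.58,16107.34
537,26495.04,17232.22
538,28277.92,18499.5
539,29751.33,19904.54
540,30842.92,21438.55
541,31496.35,23088.43
542,31675.7,24836.84
543,31368.3,26662.29
544,30585.74,28539.52
545,29362.87,30439.9
546,27755.01,32332.08
547,25833.49,34182.72
548,23680.25,35957.33
549,21381.9,37621.22
550,19023.88,39140.49
551,16685.32,40483.05
552,14434.92,41619.58
553,12328.22,42524.47
554,10406.34,43176.62
555,8696.05,43560.15
556,7211.25,43664.84
557,5955.31,43486.51
558,4924.24,43027.09
559,4110.3,42294.51
560,3505.6,41302.44
561,3105.59,40069.73
562,2911.76,38619.79
563,2933.31,36979.77
564,3187.2,35179.71
565,3696.07,33251.51
566,4483.95,31228.03
567,5569.65,29142.12
568,6958.57,27025.74
569,8634.06,24909.15
570,10550.06,22820.24
571,12626.92,20783.99
572,14752.33,18822.04
573,16788.26,16952.48
574,18583.89,15189.7
575,19992.95,13544.41
576,20892.83,12023.81
577,21201.81,10631.79
578,20891.07,9369.26
579,19989,8234.53
580,18576.78,7223.69
581,16776.34,6331.03
582,14732.9,5549.47
583,12595.81,4870.94
584,10500.98,4286.75
585,8557.67,3787.92
586,6841.32,3365.43
587,5392.27,3010.46
588,4219.58,2714.61
589,3308.01,2469.97
590,2626.35,2269.26
591,2135.43,2105.87
592,1794.59,1973.9
593,1566.32,1868.12
594,1418.74,1783.98
595,1326.6,1717.55
596,1271.02,1665.52
597,1238.61,1625.06
598,1220.35,1593.84
599,1210.39,1569.93
600,1205.15,1551.75
601,1202.47,1538.03
602,1201.15,1527.76
603,1200.52,1520.12
604,1200.23,1514.48
605,1200.1,1510.35
606,1200.04,1507.35
607,1200.02,1505.18
608,1200.01,1503.63
609,1200,1502.52
610,1200,1501.74
611,1200,1501.2
612,1200,1500.81
613,1200,1500.55
614,1200,1500.37
615,1200,1500.25
616,1200,1500.16
617,1200,1500.11
618,1200,1500.07
619,1200,1500.05
620,1200,1500.03
621,1200,1500.02
622,1200,1500.01
623,1200,1500.01
624,1200,1500
625,1200,1500
626,1200,1500
627,1200,1500
628,1200,1500
629,1200,1500
630,1200,1500
631,1200,1500
632,1200,1500
633,1200,1500
634,1200,1500
635,1200,1500
636,1200,1500
637,1200,1500
638,1200,1500
639,1200,1500
640,1200,1500
641,1200,1500
642,1200,1500
643,1200,1500
644,1200,1500
645,1200,1500
646,1200,1500
647,1200,1500
648,1200,1500
649,1200,1500
650,1200,1500
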