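# Molar extinction coefficients of human hemoglobin (L mol^-1 cm^-1),
# synthetic reconstruction: spline through literature anchor values
# (standard published compilations); see data-raw/make_extinction_table.R.
# Use with c_hb in g/L and molar mass 64500 g/mol.
wavelength_nm,eps_hbo2,eps_hb
450,62816.0,103292.0
452,57631.8,97262.9
454,52735.5,91521.9
456,48000.0,86000.0
458,43383.4,80631.1
460,39011.0,75322.9
462,35000.0,70000.0
464,31412.6,64655.3
466,28251.7,59439.3
468,25500.0,54500.0
470,23113.6,49842.3
472,20980.0,45107.6
474,19000.0,40000.0
476,17156.1,34637.4
478,15621.2,29954.1
480,14550.0,26629.0
482,14016.1,24840.0
484,13929.8,23997.4
486,14200.0,23500.0
488,14760.8,22934.1
490,15550.4,22326.6
492,16500.0,21800.0
494,17539.5,21435.6
496,18644.4,21191.5
498,19800.0,21000.0
500,20900.0,20900.0
502,21590.1,21211.1
504,21943.7,21827.3
506,22200.0,22500.0
508,22561.0,23017.5
510,23016.8,23414.9
512,23500.0,23800.0
514,23960.6,24267.8
516,24438.3,24835.3
518,25000.0,25500.0
520,25719.8,26274.8
522,26684.9,27238.6
524,28000.0,28500.0
526,29762.0,30146.6
528,31950.9,32098.0
530,34500.0,34200.0
532,37341.0,36297.2
534,40491.6,38382.6
536,44000.0,40500.0
538,47792.9,42699.7
540,51201.2,45019.8
542,53236.0,47500.0
544,53211.4,50052.0
546,52000.0,52000.0
548,50611.1,52728.6
550,49000.0,52800.0
552,46878.3,52941.0
554,43942.8,53190.3
556,40000.0,53412.0
558,35517.9,53465.4
560,32613.0,53200.0
562,32609.2,52451.0
564,34500.0,51000.0
566,37086.3,48786.8
568,40206.8,46281.1
570,44000.0,44000.0
572,48461.8,42250.0
574,52757.6,40840.3
576,55540.0,39500.0
578,55180.9,37977.3
580,50000.0,36000.0
582,40545.0,33500.3
584,31000.0,31000.0
586,23671.4,28912.6
588,18190.5,27137.7
590,14000.0,25500.0
592,10730.4,23830.6
594,8116.8,21888.2
596,6000.0,19500.0
598,4337.2,16820.4
600,3200.0,14677.0
602,2512.0,13502.6
604,2085.8,12917.3
606,1800.0,12500.0
608,1589.8,11973.0
610,1428.2,11373.7
612,1300.0,10800.0
614,1194.3,10313.0
616,1103.1,9890.6
618,1020.5,9496.5
620,942.0,9100.0
622,865.3,8681.8
624,792.0,8250.3
626,724.3,7819.1
628,663.3,7399.3
630,610.0,7000.0
632,564.4,6626.3
634,525.7,6274.2
636,492.9,5938.5
638,465.2,5614.9
640,442.0,5300.0
642,422.7,4992.8
644,406.3,4699.5
646,392.2,4426.7
648,379.7,4178.9
650,368.0,3960.0
652,356.9,3771.1
654,346.3,3607.9
656,336.6,3465.4
658,327.7,3339.7
660,320.0,3227.0
662,313.4,3124.7
664,307.8,3031.5
666,302.8,2946.7
668,298.3,2869.8
670,294.0,2800.0
672,289.8,2737.0
674,285.7,2680.5
676,282.0,2630.6
678,278.7,2587.1
680,276.0,2550.0
682,274.0,2518.0
684,272.8,2484.3
686,272.3,2441.2
688,272.7,2381.8
690,274.0,2300.0
692,276.2,2194.6
694,279.1,2078.4
696,282.5,1965.7
698,286.2,1867.8
700,290.0,1794.0
702,293.7,1749.3
704,297.6,1727.3
706,302.0,1720.0
708,307.3,1720.0
710,314.0,1720.0
712,322.4,1714.3
714,332.5,1703.0
716,343.9,1687.5
718,356.5,1669.3
720,370.0,1650.0
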