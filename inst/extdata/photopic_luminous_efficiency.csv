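# CIE 1924 photopic luminous efficiency V(lambda), peak 1 at 555 nm,
# interpolated to 1 nm by monotone Hermite spline from the 5 nm table.
wavelength_nm,value
380,3.9e-05
381,4.3504e-05
382,4.7512e-05
383,5.1768e-05
384,5.7016e-05
385,6.4e-05
386,7.256e-05
387,8.22e-05
388,9.316e-05
389,0.00010568
390,0.00012
391,0.000135464
392,0.000151912
393,0.000170328
394,0.000191696
395,0.000217
396,0.000246512
397,0.000279576
398,0.000315784
399,0.000354728
400,0.000396
401,0.000435424
402,0.000473272
403,0.000515808
404,0.000569296
405,0.00064
406,0.000726736
407,0.000825328
408,0.000937552
409,0.001065184
410,0.00121
411,0.0013648
412,0.0015284
413,0.0017116
414,0.0019252
415,0.00218
416,0.00246592
417,0.00277576
418,0.00312464
419,0.00352768
420,0.004
421,0.00454928
422,0.00516544
423,0.00583696
424,0.00655232
425,0.0073
426,0.00808096
427,0.00890288
428,0.00976432
429,0.01066384
430,0.0116
431,0.01257312
432,0.01358416
433,0.01463264
434,0.01571808
435,0.01684
436,0.01800288
437,0.01920704
438,0.02044576
439,0.02171232
440,0.023
441,0.02429664
442,0.02560672
443,0.02694848
444,0.02834016
445,0.0298
446,0.0313216
447,0.0328928
448,0.0345232
449,0.0362224
450,0.038
451,0.0398528
452,0.0417744
453,0.0437696
454,0.0458432
455,0.048
456,0.0502416
457,0.0525648
458,0.0549672
459,0.0574464
460,0.06
461,0.06260752
462,0.06527056
463,0.06801984
464,0.07088608
465,0.0739
466,0.07703984
467,0.08028512
468,0.08366848
469,0.08722256
470,0.09098
471,0.09493664
472,0.09907072
473,0.1033885
474,0.1078962
475,0.1126
476,0.117515
477,0.1226371
478,0.1279437
479,0.1334122
480,0.13902
481,0.1446939
482,0.150449
483,0.156395
484,0.1626421
485,0.1693
486,0.1763141
487,0.183611
488,0.191273
489,0.1993819
490,0.20802
491,0.2171558
492,0.2267347
493,0.2368037
494,0.2474098
495,0.2586
496,0.2702771
497,0.2824098
498,0.2951438
499,0.3086253
500,0.323
501,0.338404
502,0.35474
503,0.371804
504,0.389392
505,0.4073
506,0.4255584
507,0.4443032
508,0.4634888
509,0.4830696
510,0.503
511,0.5234864
512,0.5445592
513,0.5659088
514,0.5872256
515,0.6082
516,0.6290752
517,0.6500576
518,0.6707824
519,0.6908848
520,0.71
521,0.7280608
522,0.7453104
523,0.7618496
524,0.7777792
525,0.7932
526,0.8081368
527,0.8225224
528,0.8363196
529,0.8494912
530,0.862
531,0.87381
532,0.884946
533,0.895462
534,0.905412
535,0.91485
536,0.9237624
537,0.9321132
538,0.9399228
539,0.9472116
540,0.954
541,0.9602688
542,0.9660044
543,0.9712356
544,0.9759912
545,0.9803
546,0.9841292
547,0.9874596
548,0.9903404
549,0.9928208
550,0.99495
551,0.9967352
552,0.9981436
553,0.9991644
554,0.9997868
555,1
556,0.9998256
557,0.9992708
558,0.9983032
559,0.9968904
560,0.995
561,0.9926128
562,0.9897504
563,0.9864416
564,0.9827152
565,0.9786
566,0.9740928
567,0.9691744
568,0.9638496
569,0.9581232
570,0.952
571,0.9454608
572,0.9385024
573,0.9311536
574,0.9234432
575,0.9154
576,0.907016
577,0.898272
578,0.88918
579,0.879752
580,0.87
581,0.8598808
582,0.8493864
583,0.8385816
584,0.8275312
585,0.8163
586,0.8048432
587,0.7931176
588,0.7811904
589,0.7691288
590,0.757
591,0.744788
592,0.732448
593,0.720004
594,0.70748
595,0.6949
596,0.68224
597,0.669484
598,0.656668
599,0.643828
600,0.631
601,0.6181728
602,0.6053224
603,0.5924656
604,0.5796192
605,0.5668
606,0.5539824
607,0.5411552
608,0.5283568
609,0.5156256
610,0.503
611,0.4904864
612,0.4780592
613,0.4657088
614,0.4534256
615,0.4412
616,0.4290544
617,0.4169952
618,0.4049888
619,0.3930016
620,0.381
621,0.3689232
622,0.3567936
623,0.3447024
624,0.3327408
625,0.321
626,0.309416
627,0.297928
628,0.286632
629,0.275624
630,0.265
631,0.254792
632,0.244936
633,0.235384
634,0.226088
635,0.217
636,0.2081328
637,0.1995184
638,0.1911376
639,0.1829712
640,0.175
641,0.1672176
642,0.1596368
643,0.1522672
644,0.1451184
645,0.1382
646,0.1315088
647,0.1250384
648,0.1187936
649,0.1127792
650,0.107
651,0.101472
652,0.096192
653,0.091136
654,0.08628
655,0.0816
656,0.07710592
657,0.07281376
658,0.06870864
659,0.06477568
660,0.061
661,0.05738704
662,0.05394672
663,0.05067088
664,0.04755136
665,0.04458
666,0.04175776
667,0.03909008
668,0.03657552
669,0.03421264
670,0.032
671,0.02995648
672,0.02808304
673,0.02635136
674,0.02473312
675,0.0232
676,0.02177568
677,0.02047904
678,0.01927456
679,0.01812672
680,0.017
681,0.0158904
682,0.0148216
683,0.0137996
684,0.0128304
685,0.01192
686,0.01107075
687,0.01027866
688,0.009540184
689,0.008851808
690,0.00821
691,0.007620472
692,0.007085576
693,0.006596744
694,0.006145408
695,0.005723
696,0.005336208
697,0.004990744
698,0.004676576
699,0.004383672
700,0.004102
701,0.003833368
702,0.003584464
703,0.003352576
704,0.003134992
705,0.002929
706,0.002736264
707,0.002558592
708,0.002393488
709,0.002238456
710,0.002091
711,0.001952096
712,0.001823408
713,0.001703472
714,0.001590824
715,0.001484
716,0.00138364
717,0.00129072
718,0.00120428
719,0.00112336
720,0.001047
721,0.000975888
722,0.000910664
723,0.000850296
724,0.000793752
725,0.00074
726,0.000689456
727,0.000642808
728,0.000599432
729,0.000558704
730,0.00052
731,0.000483544
732,0.000449752
733,0.000418288
734,0.000388816
735,0.000361
736,0.000335032
737,0.000311136
738,0.000289024
739,0.000268408
740,0.000249
741,0.00023096
742,0.00021448
743,0.00019932
744,0.00018524
745,0.000172
746,0.0001597312
747,0.0001485936
748,0.0001383904
749,0.0001289248
750,0.00012
751,0.0001117184
752,0.0001042112
753,9.73248e-05
754,9.09056e-05
755,8.48e-05
756,7.90592e-05
757,7.37856e-05
758,6.89024e-05
759,6.43328e-05
760,6e-05
761,5.5936e-05
762,5.2192e-05
763,4.872e-05
764,4.5472e-05
765,4.24e-05
766,3.95296e-05
767,3.68928e-05
768,3.44512e-05
769,3.21664e-05
770,3e-05
771,2.79696e-05
772,2.61008e-05
773,2.43672e-05
774,2.27424e-05
775,2.12e-05
776,1.978e-05
777,1.85e-05
778,1.73e-05
779,1.612e-05
780,1.49e-05
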