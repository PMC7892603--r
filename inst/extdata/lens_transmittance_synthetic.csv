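# Synthetic standard-observer-style crystalline lens transmittance.
# Constructed from hand-set optical-density anchors (monotone Hermite
# interpolation); transmittance = 10^(-density). Not a published table.
wavelength_nm,value
380,0.01
381,0.01136187
382,0.01293004
383,0.01472821
384,0.01678031
385,0.01910953
386,0.02173702
387,0.02468028
388,0.02795117
389,0.03155368
390,0.03548134
391,0.03979789
392,0.04459437
393,0.04989075
394,0.05569805
395,0.06201546
396,0.06882718
397,0.07609918
398,0.08377607
399,0.0917783
400,0.1
401,0.1083166
402,0.1166702
403,0.1250446
404,0.1334381
405,0.1418649
406,0.1503557
407,0.158959
408,0.1677413
409,0.1767889
410,0.1862087
411,0.1958258
412,0.2053809
413,0.214877
414,0.2243262
415,0.2337491
416,0.2431756
417,0.2526446
418,0.2622044
419,0.271913
420,0.2818383
421,0.2918804
422,0.3018839
423,0.3118423
424,0.3217511
425,0.331608
426,0.341413
427,0.3511681
428,0.3608777
429,0.3705484
430,0.3801894
431,0.3896817
432,0.3989147
433,0.4079153
434,0.4167158
435,0.4253535
436,0.4338704
437,0.4423133
438,0.4507337
439,0.4591874
440,0.4677351
441,0.4763213
442,0.4848417
443,0.4932874
444,0.5016491
445,0.5099176
446,0.5180838
447,0.5261384
448,0.5340722
449,0.5418761
450,0.5495409
451,0.5569997
452,0.564209
453,0.5711958
454,0.5779896
455,0.5846218
456,0.5911259
457,0.5975373
458,0.603893
459,0.610232
460,0.616595
461,0.6229454
462,0.6292164
463,0.6354041
464,0.6415049
465,0.6475152
466,0.6534314
467,0.6592498
468,0.6649669
469,0.6705791
470,0.676083
471,0.6814751
472,0.6867521
473,0.6919106
474,0.6969474
475,0.7018592
476,0.7066429
477,0.7112954
478,0.7158137
479,0.7201948
480,0.724436
481,0.7284588
482,0.7322173
483,0.735758
484,0.7391286
485,0.7423778
486,0.7455555
487,0.7487124
488,0.7518999
489,0.7551705
490,0.7585776
491,0.7621185
492,0.7657376
493,0.7694094
494,0.7731077
495,0.7768059
496,0.7804768
497,0.7840929
498,0.7876259
499,0.7910474
500,0.7943282
501,0.7974482
502,0.8004238
503,0.803281
504,0.8060463
505,0.8087467
506,0.8114093
507,0.814062
508,0.8167328
509,0.8194501
510,0.8222426
511,0.8251302
512,0.8280947
513,0.8311081
514,0.834142
515,0.8371678
516,0.8401561
517,0.8430775
518,0.8459019
519,0.848599
520,0.851138
521,0.853498
522,0.855697
523,0.8577634
524,0.8597259
525,0.8616135
526,0.8634556
527,0.8652817
528,0.8671216
529,0.8690054
530,0.8709636
531,0.8729895
532,0.8750482
533,0.8771281
534,0.8792168
535,0.8813025
536,0.8833728
537,0.8854153
538,0.8874175
539,0.889367
540,0.8912509
541,0.8930793
542,0.8948701
543,0.8966233
544,0.8983385
545,0.9000155
546,0.9016542
547,0.9032542
548,0.9048154
549,0.9063376
550,0.9078205
551,0.9092452
552,0.9106007
553,0.9118995
554,0.9131539
555,0.9143764
556,0.9155794
557,0.9167755
558,0.9179774
559,0.9191979
560,0.9204496
561,0.9217412
562,0.9230644
563,0.9244065
564,0.9257549
565,0.9270966
566,0.928419
567,0.9297089
568,0.9309535
569,0.9321397
570,0.9332543
571,0.9342885
572,0.9352506
573,0.9361534
574,0.9370095
575,0.9378319
576,0.9386334
577,0.9394269
578,0.9402254
579,0.941042
580,0.9418896
581,0.9427673
582,0.943661
583,0.9445642
584,0.9454705
585,0.9463733
586,0.9472661
587,0.9481423
588,0.9489952
589,0.9498182
590,0.9506048
591,0.9513504
592,0.9520593
593,0.952738
594,0.9533931
595,0.954031
596,0.9546584
597,0.9552818
598,0.9559078
599,0.956543
600,0.9571941
601,0.9578607
602,0.9585373
603,0.959222
604,0.9599133
605,0.9606095
606,0.961309
607,0.9620101
608,0.9627111
609,0.9634105
610,0.9641065
611,0.9647974
612,0.9654816
613,0.9661574
614,0.9668231
615,0.9674769
616,0.9681173
617,0.9687425
618,0.9693509
619,0.9699406
620,0.97051
621,0.9710606
622,0.9715955
623,0.9721157
624,0.9726218
625,0.9731148
626,0.9735954
627,0.9740644
628,0.9745228
629,0.9749713
630,0.9754107
631,0.9758418
632,0.9762656
633,0.9766829
634,0.9770943
635,0.9775009
636,0.9779035
637,0.9783028
638,0.9786998
639,0.9790952
640,0.97949
641,0.9798819
642,0.9802684
643,0.9806494
644,0.9810248
645,0.9813948
646,0.9817592
647,0.9821182
648,0.9824716
649,0.9828195
650,0.9831618
651,0.9834986
652,0.9838299
653,0.9841556
654,0.9844757
655,0.9847903
656,0.9850993
657,0.9854027
658,0.9857006
659,0.9859928
660,0.9862795
661,0.9865606
662,0.986836
663,0.9871059
664,0.9873702
665,0.9876288
666,0.9878818
667,0.9881292
668,0.988371
669,0.9886072
670,0.9888377
671,0.9890625
672,0.9892818
673,0.9894953
674,0.9897033
675,0.9899055
676,0.9901021
677,0.9902931
678,0.9904784
679,0.990658
680,0.9908319
681,0.9909975
682,0.9911525
683,0.9912979
684,0.9914344
685,0.991563
686,0.9916844
687,0.9917996
688,0.9919094
689,0.9920146
690,0.9921161
691,0.9922148
692,0.9923114
693,0.992407
694,0.9925023
695,0.9925981
696,0.9926954
697,0.992795
698,0.9928977
699,0.9930044
700,0.993116
701,0.9932304
702,0.9933447
703,0.9934591
704,0.9935735
705,0.9936879
706,0.9938023
707,0.9939167
708,0.9940312
709,0.9941456
710,0.9942601
711,0.9943745
712,0.994489
713,0.9946035
714,0.9947181
715,0.9948326
716,0.9949471
717,0.9950617
718,0.9951762
719,0.9952908
720,0.9954054
721,0.9955214
722,0.9956398
723,0.9957602
724,0.9958823
725,0.9960055
726,0.9961294
727,0.9962536
728,0.9963777
729,0.9965012
730,0.9966238
731,0.9967449
732,0.9968642
733,0.9969812
734,0.9970955
735,0.9972066
736,0.9973142
737,0.9974178
738,0.9975169
739,0.9976111
740,0.9977001
741,0.9977834
742,0.9978615
743,0.9979346
744,0.9980034
745,0.9980681
746,0.9981292
747,0.9981871
748,0.9982424
749,0.9982953
750,0.9983464
751,0.998396
752,0.9984447
753,0.9984927
754,0.9985407
755,0.9985889
756,0.9986378
757,0.9986879
758,0.9987396
759,0.9987932
760,0.9988494
761,0.9989069
762,0.9989644
763,0.9990219
764,0.9990794
765,0.9991369
766,0.9991944
767,0.9992519
768,0.9993095
769,0.999367
770,0.9994245
771,0.9994821
772,0.9995396
773,0.9995971
774,0.9996547
775,0.9997122
776,0.9997698
777,0.9998273
778,0.9998849
779,0.9999424
780,1
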