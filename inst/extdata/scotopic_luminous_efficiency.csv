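# CIE 1951 scotopic luminous efficiency V'(lambda), peak 1 at 507 nm,
# interpolated to 1 nm by monotone Hermite spline from the 5 nm table.
wavelength_nm,value
380,0.000589
381,0.000683488
382,0.000768664
383,0.000858496
384,0.000966952
385,0.001108
386,0.001271432
387,0.001447936
388,0.001652824
389,0.001901408
390,0.002209
391,0.002556096
392,0.002932488
393,0.003367432
394,0.003890184
395,0.00453
396,0.005254384
397,0.006043832
398,0.006947088
399,0.008012896
400,0.00929
401,0.01073648
402,0.01231984
403,0.01410296
404,0.01614872
405,0.01852
406,0.0211824
407,0.024094
408,0.0273064
409,0.0308712
410,0.03484
411,0.0391904
412,0.043888
413,0.0489664
414,0.0544592
415,0.0604
416,0.06678624
417,0.07359552
418,0.08083168
419,0.08849856
420,0.0966
421,0.1051616
422,0.1141808
423,0.1236192
424,0.1334384
425,0.1436
426,0.1541472
427,0.1651056
428,0.1764104
429,0.1879968
430,0.1998
431,0.2118776
432,0.2242728
433,0.2368992
434,0.2496704
435,0.2625
436,0.275444
437,0.28856
438,0.301764
439,0.314972
440,0.3281
441,0.341188
442,0.354292
443,0.367352
444,0.380308
445,0.3931
446,0.4057408
447,0.4182704
448,0.4306696
449,0.4429192
450,0.455
451,0.4669136
452,0.4786728
453,0.4902752
454,0.5017184
455,0.513
456,0.524072
457,0.534936
458,0.545664
459,0.556328
460,0.567
461,0.577616
462,0.588128
463,0.598632
464,0.609224
465,0.62
466,0.630976
467,0.642088
468,0.653312
469,0.664624
470,0.676
471,0.687456
472,0.699008
473,0.710632
474,0.722304
475,0.734
476,0.745752
477,0.757576
478,0.769424
479,0.781248
480,0.793
481,0.804744
482,0.816512
483,0.828208
484,0.839736
485,0.851
486,0.862048
487,0.872944
488,0.883616
489,0.893992
490,0.904
491,0.913704
492,0.923152
493,0.932248
494,0.940896
495,0.949
496,0.95664
497,0.96388
498,0.9706
499,0.97668
500,0.982
501,0.986464
502,0.990152
503,0.993208
504,0.995776
505,0.998
506,0.999525
507,1
508,0.9998222
509,0.9989778
510,0.997
511,0.993976
512,0.990288
513,0.985912
514,0.980824
515,0.975
516,0.968392
517,0.961016
518,0.952944
519,0.944248
520,0.935
521,0.925184
522,0.914752
523,0.903728
524,0.892136
525,0.88
526,0.86724
527,0.85384
528,0.83992
529,0.8256
530,0.811
531,0.796056
532,0.780688
533,0.764992
534,0.749064
535,0.733
536,0.716768
537,0.700304
538,0.683656
539,0.666872
540,0.65
541,0.632944
542,0.615672
543,0.598328
544,0.581056
545,0.564
546,0.547144
547,0.530392
548,0.513768
549,0.497296
550,0.481
551,0.4648512
552,0.4488336
553,0.4329904
554,0.4173648
555,0.402
556,0.386856
557,0.371904
558,0.357204
559,0.342816
560,0.3288
561,0.3151512
562,0.3018296
563,0.2888424
564,0.2761968
565,0.2639
566,0.2519472
567,0.2403336
568,0.2290664
569,0.2181528
570,0.2076
571,0.197416
572,0.187596
573,0.178128
574,0.169
575,0.1602
576,0.1517392
577,0.1436256
578,0.1358424
579,0.1283728
580,0.1212
581,0.1143368
582,0.1077944
583,0.1015536
584,0.0955952
585,0.0899
586,0.0844856
587,0.0793648
588,0.0745112
589,0.0698984
590,0.0655
591,0.0613312
592,0.0574096
593,0.0537124
594,0.0502168
595,0.0469
596,0.04378008
597,0.04087224
598,0.03814936
599,0.03558432
600,0.03315
601,0.03086048
602,0.02873384
603,0.02674896
604,0.02488472
605,0.02312
606,0.021466
607,0.0199368
608,0.0185156
609,0.0171856
610,0.01593
611,0.0147584
612,0.013682
613,0.0126864
614,0.0117572
615,0.01088
616,0.01006168
617,0.00931184
618,0.00862016
619,0.00797632
620,0.00737
621,0.00680672
622,0.00629336
623,0.00582164
624,0.00538328
625,0.00497
626,0.00458548
627,0.00423524
628,0.00391376
629,0.00361552
630,0.003335
631,0.003074968
632,0.002839104
633,0.002623256
634,0.002423272
635,0.002235
636,0.002060296
637,0.001901928
638,0.001757112
639,0.001623064
640,0.001497
641,0.001380232
642,0.001274616
643,0.001178184
644,0.001088968
645,0.001005
646,0.000927144
647,0.000856712
648,0.000792408
649,0.000732936
650,0.000677
651,0.0006252096
652,0.0005784288
653,0.0005357432
654,0.0004962384
655,0.000459
656,0.0004244136
657,0.0003930888
658,0.0003644472
659,0.0003379104
660,0.0003129
661,0.0002896736
662,0.0002686168
663,0.0002493432
664,0.0002314664
665,0.0002146
666,0.000198912
667,0.00018466
668,0.000171592
669,0.000159456
670,0.000148
671,0.0001373344
672,0.0001276272
673,0.0001187128
674,0.0001104256
675,0.0001026
676,9.53096e-05
677,8.86648e-05
678,8.25552e-05
679,7.68704e-05
680,7.15e-05
681,6.64936e-05
682,6.19248e-05
683,5.77192e-05
684,5.38024e-05
685,5.01e-05
686,4.66456e-05
687,4.34888e-05
688,4.05792e-05
689,3.78664e-05
690,3.53e-05
691,3.29024e-05
692,3.07072e-05
693,2.86808e-05
694,2.67896e-05
695,2.5e-05
696,2.3328e-05
697,2.1796e-05
698,2.038e-05
699,1.9056e-05
700,1.78e-05
701,1.662096e-05
702,1.553488e-05
703,1.452832e-05
704,1.358784e-05
705,1.27e-05
706,1.187312e-05
707,1.111616e-05
708,1.041664e-05
709,9.76208e-06
710,9.14e-06
711,8.5552e-06
712,8.016e-06
713,7.5152e-06
714,7.0456e-06
715,6.6e-06
716,6.1816e-06
717,5.7952e-06
718,5.436e-06
719,5.0992e-06
720,4.78e-06
721,4.48096e-06
722,4.20528e-06
723,3.94912e-06
724,3.70864e-06
725,3.48e-06
726,3.2648e-06
727,3.0656e-06
728,2.88e-06
729,2.7056e-06
730,2.54e-06
731,2.38432e-06
732,2.24016e-06
733,2.10584e-06
734,1.97968e-06
735,1.86e-06
736,1.74776e-06
737,1.64408e-06
738,1.54752e-06
739,1.45664e-06
740,1.37e-06
741,1.28808e-06
742,1.21184e-06
743,1.14056e-06
744,1.07352e-06
745,1.01e-06
746,9.5048e-07
747,8.9544e-07
748,8.4416e-07
749,7.9592e-07
750,7.5e-07
751,7.0672e-07
752,6.6656e-07
753,6.2904e-07
754,5.9368e-07
755,5.6e-07
756,5.2832e-07
757,4.9896e-07
758,4.7144e-07
759,4.4528e-07
760,4.2e-07
761,3.956e-07
762,3.724e-07
763,3.504e-07
764,3.296e-07
765,3.1e-07
766,2.916e-07
767,2.744e-07
768,2.584e-07
769,2.436e-07
770,2.3e-07
771,2.1792e-07
772,2.0736e-07
773,1.9784e-07
774,1.8888e-07
775,1.8e-07
776,1.7136e-07
777,1.6328e-07
778,1.5552e-07
779,1.4784e-07
780,1.4e-07
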