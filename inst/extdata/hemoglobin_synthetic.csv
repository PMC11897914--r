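wavelength_nm,mu_hbo2_cm1,mu_hb_cm1
450,336.00000,557.00000
452,298.46400,515.34400
454,262.75200,484.15200
456,230.20800,460.08800
458,202.17600,439.81600
460,180.00000,420.00000
462,165.28000,402.19200
464,157.12000,388.61600
466,153.12000,376.94400
468,150.88000,364.84800
470,148.00000,350.00000
472,144.97600,331.76000
474,143.40800,311.68000
476,142.55200,290.72000
478,141.66400,269.84000
480,140.00000,250.00000
482,137.46800,230.88000
484,134.56400,211.84000
486,131.42600,193.36000
488,128.19200,175.92000
490,125.00000,160.00000
492,121.37500,144.76562
494,117.37500,130.37500
496,113.93750,118.79688
498,112.00000,112.00000
500,111.90625,111.57812
502,113.12500,116.12500
504,115.28125,123.10938
506,118.00000,130.00000
508,121.52344,136.42188
510,125.93750,143.62500
512,130.63281,151.51562
514,135.00000,160.00000
516,137.83594,169.64844
518,139.81250,180.31250
520,143.13281,190.82031
522,150.00000,200.00000
524,161.92969,207.51562
526,177.43750,214.00000
528,194.22656,219.73438
530,210.00000,225.00000
532,224.48857,229.64000
534,238.45143,233.57000
536,251.79155,237.18000
538,266.40233,240.86000
540,278.87512,245.00000
542,285.00000,249.69531
544,281.61376,254.68750
546,271.64021,259.83594
548,260.00000,265.00000
550,247.77778,270.85938
552,233.88889,277.25000
554,220.00000,282.76562
556,204.07407,286.00000
558,188.14815,286.36111
560,180.00000,284.30556
562,183.70370,280.00000
564,195.18519,273.57812
566,210.00000,265.33333
568,229.82143,255.67188
570,250.00000,245.00000
572,266.82216,232.45370
574,282.12828,218.37963
576,290.32070,205.00000
578,286.28280,193.35938
580,270.75802,182.50000
582,247.45870,171.64062
584,220.00000,160.00000
586,185.55556,146.57407
588,145.55556,132.45370
590,110.00000,120.00000
592,82.38889,110.51852
594,59.22222,102.70370
596,40.00000,95.00000
598,25.87083,86.68333
600,17.00000,79.00000
602,11.60880,72.27200
604,8.64640,65.93600
606,7.22960,60.06400
608,6.47520,54.72800
610,5.50000,50.00000
612,4.42400,45.94400
614,3.83600,42.51200
616,3.55600,39.60800
618,3.40400,37.13600
620,3.20000,35.00000
622,2.93825,33.17965
624,2.72800,31.68320
626,2.56175,30.45755
628,2.43200,29.44960
630,2.33125,28.60625
632,2.25200,27.87440
634,2.18675,27.20095
636,2.12800,26.53280
638,2.06825,25.81685
640,2.00000,25.00000
642,1.93310,24.11930
644,1.88080,23.25040
646,1.84070,22.39810
648,1.81040,21.56720
650,1.78750,20.76250
652,1.76960,19.98880
654,1.75430,19.25090
656,1.73920,18.55360
658,1.72190,17.90170
660,1.70000,17.30000
662,1.67325,16.75845
664,1.64400,16.27760
666,1.61375,15.84815
668,1.58400,15.46080
670,1.55625,15.10625
672,1.53200,14.77520
674,1.51275,14.45835
676,1.50000,14.14640
678,1.49525,13.83005
680,1.50000,13.50000
682,1.51570,13.15860
684,1.54160,12.81680
686,1.57590,12.47820
688,1.61680,12.14640
690,1.66250,11.82500
692,1.71120,11.51760
694,1.76110,11.22780
696,1.81040,10.95920
698,1.85730,10.71540
700,1.90000,10.50000
702,1.94000,10.31315
704,1.98000,10.15120
706,2.02000,10.01205
708,2.06000,9.89360
710,2.10000,9.79375
712,2.14000,9.71040
714,2.18000,9.64145
716,2.22000,9.58480
718,2.26000,9.53835
720,2.30000,9.50000
722,2.34000,9.47476
724,2.38000,9.46760
726,2.42000,9.47634
728,2.46000,9.49880
730,2.50000,9.53281
732,2.54000,9.57620
734,2.58000,9.62679
736,2.62000,9.68240
738,2.66000,9.74086
740,2.70000,9.80000
742,2.73910,9.88590
744,2.77680,10.01263
746,2.81370,10.16002
748,2.85040,10.30786
750,2.88750,10.43597
752,2.92560,10.52415
754,2.96530,10.55223
756,3.00720,10.50000
758,3.05190,10.35430
760,3.10000,10.12871
762,3.15142,9.84315
764,3.20551,9.51757
766,3.26196,9.17189
768,3.32052,8.82606
770,3.38088,8.50000
772,3.44278,8.18166
774,3.50592,7.84916
776,3.57002,7.50771
778,3.63481,7.16252
780,3.70000,6.81878
782,3.76652,6.48171
784,3.83517,6.15652
786,3.90547,5.84095
788,3.97693,5.50324
790,4.04907,5.16093
792,4.12142,4.83988
794,4.19348,4.56596
796,4.26479,4.36502
798,4.33532,4.25092
800,4.40744,4.16699
802,4.48098,4.10017
804,4.55530,4.04821
806,4.62974,4.00889
808,4.70366,3.97998
810,4.77642,3.95925
812,4.84735,3.94445
814,4.91583,3.93336
816,4.98119,3.92374
818,5.04280,3.91337
820,5.10000,3.90000
822,5.15329,3.88365
824,5.20375,3.86607
826,5.25158,3.84764
828,5.29701,3.82874
830,5.34026,3.80977
832,5.38153,3.79109
834,5.42105,3.77311
836,5.45903,3.75619
838,5.49569,3.74073
840,5.53124,3.72711
842,5.56590,3.71570
844,5.59990,3.70691
846,5.63343,3.70110
848,5.66673,3.69867
850,5.70000,3.70000
852,5.73237,3.70579
854,5.76296,3.71612
856,5.79200,3.73040
858,5.81970,3.74806
860,5.84630,3.76852
862,5.87200,3.79120
864,5.89704,3.81553
866,5.92163,3.84092
868,5.94600,3.86680
870,5.97037,3.89259
872,5.99496,3.91772
874,6.02000,3.94160
876,6.04570,3.96366
878,6.07230,3.98332
880,6.10000,4.00000
882,6.12955,4.01518
884,6.16107,4.03040
886,6.19385,4.04523
888,6.22720,4.05920
890,6.26042,4.07187
892,6.29280,4.08280
894,6.32365,4.09152
896,6.35227,4.09760
898,6.37795,4.10057
900,6.40000,4.10000
902,6.41942,4.09719
904,6.43770,4.09370
906,6.45486,4.08943
908,6.47093,4.08427
910,6.48594,4.07812
912,6.49990,4.07090
914,6.51285,4.06249
916,6.52480,4.05280
918,6.53579,4.04172
920,6.54583,4.02917
922,6.55496,4.01502
924,6.56320,3.99920
926,6.57057,3.98159
928,6.57710,3.96210
930,6.58281,3.94062
932,6.58773,3.91707
934,6.59189,3.89132
936,6.59530,3.86330
938,6.59800,3.83289
940,6.60000,3.80000
942,6.60142,3.76316
944,6.60227,3.72136
946,6.60240,3.67520
948,6.60169,3.62529
950,6.60000,3.57222
952,6.59720,3.51660
954,6.59316,3.45902
956,6.58773,3.40009
958,6.58080,3.34040
960,6.57222,3.28056
962,6.56187,3.22116
964,6.54960,3.16280
966,6.53529,3.10609
968,6.51880,3.05162
970,6.50000,3.00000
972,6.47828,2.95043
974,6.45336,2.90166
976,6.42560,2.85360
978,6.39535,2.80616
980,6.36296,2.75926
982,6.32880,2.71280
984,6.29321,2.66670
986,6.25656,2.62086
988,6.21920,2.57520
990,6.18148,2.52963
992,6.14376,2.48406
994,6.10640,2.43840
996,6.06975,2.39256
998,6.03416,2.34646
1000,6.00000,2.30000
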