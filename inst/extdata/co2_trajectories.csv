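scenario,year,ppm
RCP2.6,2000,369
RCP2.6,2010,390
RCP2.6,2020,412
RCP2.6,2030,431
RCP2.6,2040,440
RCP2.6,2050,443
RCP2.6,2060,442
RCP2.6,2070,437
RCP2.6,2080,432
RCP2.6,2090,426
RCP2.6,2100,421
RCP4.5,2000,369
RCP4.5,2010,389
RCP4.5,2020,411
RCP4.5,2030,435
RCP4.5,2040,461
RCP4.5,2050,487
RCP4.5,2060,509
RCP4.5,2070,524
RCP4.5,2080,531
RCP4.5,2090,534
RCP4.5,2100,538
RCP6.0,2000,369
RCP6.0,2010,389
RCP6.0,2020,409
RCP6.0,2030,429
RCP6.0,2040,451
RCP6.0,2050,478
RCP6.0,2060,510
RCP6.0,2070,545
RCP6.0,2080,584
RCP6.0,2090,620
RCP6.0,2100,670
RCP8.5,2000,369
RCP8.5,2010,390
RCP8.5,2020,416
RCP8.5,2030,449
RCP8.5,2040,489
RCP8.5,2050,540
RCP8.5,2060,604
RCP8.5,2070,677
RCP8.5,2080,758
RCP8.5,2090,845
RCP8.5,2100,936
A2,2000,369
A2,2010,390
A2,2020,417
A2,2030,451
A2,2040,491
A2,2050,532
A2,2060,581
A2,2070,637
A2,2080,698
A2,2090,771
A2,2100,856
A1B,2000,369
A1B,2010,391
A1B,2020,420
A1B,2030,454
A1B,2040,491
A1B,2050,532
A1B,2060,572
A1B,2070,611
A1B,2080,649
A1B,2090,685
A1B,2100,717
B1,2000,369
B1,2010,388
B1,2020,408
B1,2030,429
B1,2040,447
B1,2050,463
B1,2060,478
B1,2070,492
B1,2080,504
B1,2090,513
B1,2100,522
other,2000,369
other,2010,390
other,2020,410
other,2030,430
other,2040,450
other,2050,470
other,2060,490
other,2070,510
other,2080,530
other,2090,550
other,2100,570
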