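Date,Close
2020-01-03,100.765
2020-01-04,100.4014
2020-01-05,103.5744
2020-01-06,102.6836
2020-01-07,102.6181
2020-01-08,99.3192
2020-01-09,97.6416
2020-01-10,99.8598
2020-01-11,103.3431
2020-01-12,98.8827
2020-01-13,99.722
2020-01-14,100.2587
2020-01-15,99.1701
2020-01-16,96.7075
2020-01-17,96.4336
2020-01-18,97.7823
2020-01-19,102.6467
2020-01-20,102.2739
2020-01-21,105.8259
2020-01-22,103.6118
2020-01-23,106.1263
2020-01-24,107.4403
2020-01-25,104.0815
2020-01-26,103.2982
2020-01-27,104.0189
2020-01-28,99.4922
2020-01-29,97.7103
2020-01-30,99.1472
2020-01-31,98.8718
2020-02-01,99.6808
2020-02-02,99.8907
2020-02-03,99.084
2020-02-04,98.9065
2020-02-05,99.7531
2020-02-06,103.3013
2020-02-07,102.7854
2020-02-08,101.7102
2020-02-09,101.6388
2020-02-10,108.3034
2020-02-11,110.0283
2020-02-12,114.3004
2020-02-13,113.2693
2020-02-14,113.0885
2020-02-15,111.6657
2020-02-16,111.5658
2020-02-17,111.106
2020-02-18,109.7953
2020-02-19,108.5144
2020-02-20,108.9586
2020-02-21,107.5131
2020-02-22,106.6524
2020-02-23,106.5844
2020-02-24,107.5944
2020-02-25,108.0307
2020-02-26,107.9526
2020-02-27,107.994
2020-02-28,103.1439
2020-02-29,104.3373
2020-03-01,105.1112
2020-03-02,104.3821
2020-03-03,104.6349
2020-03-04,105.821
2020-03-05,107.547
2020-03-06,104.6918
2020-03-07,105.5981
2020-03-08,103.8222
2020-03-09,103.7055
2020-03-10,104.2392
2020-03-11,103.8089
2020-03-12,101.2335
2020-03-13,104.1284
2020-03-14,105.5322
2020-03-15,105.7424
2020-03-16,106.4859
2020-03-17,109.2806
2020-03-18,104.7912
2020-03-19,102.4116
2020-03-20,102.8853
2020-03-21,104.2287
2020-03-22,104.3077
2020-03-23,101.728
2020-03-24,99.3968
2020-03-25,101.9561
2020-03-26,103.4606
2020-03-27,102.5462
2020-03-28,104.8309
2020-03-29,105.2767
2020-03-30,105.643
2020-03-31,106.8764
2020-04-01,107.4222
2020-04-02,108.9234
2020-04-03,111.1002
2020-04-04,112.738
2020-04-05,113.9282
2020-04-06,116.3783
2020-04-07,114.7772
2020-04-08,111.9215
2020-04-09,113.2354
2020-04-10,114.3037
2020-04-11,113.5116
2020-04-12,111.2961
2020-04-13,109.4847
2020-04-14,108.9884
2020-04-15,111.9817
2020-04-16,111.2173
2020-04-17,113.5307
2020-04-18,114.4621
2020-04-19,114.123
2020-04-20,115.4552
2020-04-21,116.6733
2020-04-22,117.9603
2020-04-23,119.0333
2020-04-24,121.4722
2020-04-25,123.9351
2020-04-26,126.4132
2020-04-27,121.004
2020-04-28,125.012
2020-04-29,122.3898
2020-04-30,123.1193
2020-05-01,119.6668
2020-05-02,121.8322
2020-05-03,125.8251
2020-05-04,126.5179
2020-05-05,131.1301
2020-05-06,125.5261
2020-05-07,122.7981
2020-05-08,122.2253
2020-05-09,123.3692
2020-05-10,124.9914
2020-05-11,125.4075
2020-05-12,131.486
2020-05-13,136.4468
2020-05-14,133.5244
2020-05-15,119.5917
2020-05-16,117.1291
2020-05-17,109.4268
2020-05-18,106.3427
2020-05-19,106.0608
2020-05-20,109.3094
2020-05-21,105.9634
2020-05-22,89.6598
2020-05-23,82.5057
2020-05-24,86.8128
2020-05-25,84.3707
2020-05-26,86.2217
2020-05-27,92.8212
2020-05-28,113.1089
2020-05-29,119.6059
2020-05-30,121.5615
2020-05-31,125.3688
2020-06-01,116.7336
2020-06-02,124.295
2020-06-03,115.7783
2020-06-04,115.1791
2020-06-05,100.9599
2020-06-06,103.3096
2020-06-07,107.9629
2020-06-08,117.7969
2020-06-09,110.9317
2020-06-10,115.0671
2020-06-11,118.3405
2020-06-12,114.6023
2020-06-13,113.5231
2020-06-14,115.4254
2020-06-15,115.5108
2020-06-16,113.3981
2020-06-17,117.9068
2020-06-18,114.4502
2020-06-19,114.9887
2020-06-20,112.3466
2020-06-21,111.1138
2020-06-22,114.4635
2020-06-23,115.2914
2020-06-24,116.334
2020-06-25,117.8825
2020-06-26,120.3844
2020-06-27,122.3854
2020-06-28,120.5075
2020-06-29,125.5219
2020-06-30,127.4774
2020-07-01,125.3571
2020-07-02,126.2937
2020-07-03,120.8982
2020-07-04,119.3507
2020-07-05,118.1749
2020-07-06,116.3886
2020-07-07,117.3854
2020-07-08,116.4497
2020-07-09,114.1603
2020-07-10,111.7314
2020-07-11,113.529
2020-07-12,117.7909
2020-07-13,115.5249
2020-07-14,113.3186
2020-07-15,112.5021
2020-07-16,109.4768
2020-07-17,108.2991
2020-07-18,108.4806
2020-07-19,109.433
2020-07-20,107.6988
2020-07-21,107.1204
2020-07-22,106.9938
2020-07-23,108.4617
2020-07-24,102.5484
2020-07-25,102.4218
2020-07-26,104.4828
2020-07-27,104.9346
2020-07-28,102.2209
2020-07-29,104.9805
2020-07-30,102.7365
2020-07-31,102.5359
2020-08-01,101.5554
2020-08-02,104.2878
2020-08-03,105.9857
2020-08-04,102.7159
2020-08-05,102.4088
2020-08-06,105.265
2020-08-07,105.3114
2020-08-08,107.2739
2020-08-09,105.9872
2020-08-10,105.2604
2020-08-11,101.4412
2020-08-12,101.6727
2020-08-13,103.8265
2020-08-14,105.6623
2020-08-15,108.1954
2020-08-16,107.9696
2020-08-17,106.2223
2020-08-18,103.1548
2020-08-19,103.7131
2020-08-20,103.683
2020-08-21,99.9773
2020-08-22,102.4014
2020-08-23,99.5954
2020-08-24,101.3037
2020-08-25,102.0294
2020-08-26,102.0792
2020-08-27,96.943
2020-08-28,98.0933
2020-08-29,98.4184
2020-08-30,98.2248
2020-08-31,97.1638
2020-09-01,96.6267
2020-09-02,94.622
2020-09-03,95.2142
2020-09-04,95.147
2020-09-05,94.3032
2020-09-06,94.7894
2020-09-07,93.2848
2020-09-08,92.6205
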