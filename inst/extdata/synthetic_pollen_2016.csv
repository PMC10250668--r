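date,grains_m3
2016-04-13,3
2016-04-14,4
2016-04-15,3
2016-04-16,10
2016-04-17,3
2016-04-18,6
2016-04-19,4
2016-04-20,7
2016-04-21,6
2016-04-22,13
2016-04-23,24
2016-04-24,80
2016-04-25,46
2016-04-26,51
2016-04-27,37
2016-04-28,86
2016-04-29,49
2016-04-30,45
2016-05-01,45
2016-05-02,66
2016-05-03,57
2016-05-04,95
2016-05-05,85
2016-05-06,135
2016-05-07,68
2016-05-08,89
2016-05-09,128
2016-05-10,158
2016-05-11,199
2016-05-12,100
2016-05-13,63
2016-05-14,106
2016-05-15,199
2016-05-16,119
2016-05-17,91
2016-05-18,76
2016-05-19,193
2016-05-20,76
2016-05-21,50
2016-05-22,75
2016-05-23,59
2016-05-24,76
2016-05-25,62
2016-05-26,27
2016-05-27,17
2016-05-28,70
2016-05-29,18
2016-05-30,56
2016-05-31,27
2016-06-01,13
2016-06-02,10
2016-06-03,13
2016-06-04,19
2016-06-05,8
2016-06-06,5
2016-06-07,8
2016-06-08,3
2016-06-09,6
2016-06-10,1
2016-06-11,1
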