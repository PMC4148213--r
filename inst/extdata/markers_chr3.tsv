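marker	chrom	pos
ss317369158	3	70119483
rs16294399	3	70201106
rs16294517	3	70299532
ss317369395	3	70311973
rs15380516	3	70367159
rs16294597	3	70367382
rs16294606	3	70377047
rs16294615	3	70383717
rs14372495	3	70384172
rs14372520	3	70399176
ss666793689	3	70412158
rs14372560	3	70422653
rs16294682	3	70441580
rs16294701	3	70447648
rs16294719	3	70461007
rs13691298	3	70467968
rs16294744	3	70481788
rs14372652	3	70504365
rs14372671	3	70527941
ss317369621	3	70558349
ss317369629	3	70581126
rs10724747	3	70640111
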