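SAMPLING EVENT IDENTIFIER	SPECIES CODE	OBSERVATION COUNT	LATITUDE	LONGITUDE	OBSERVATION DATE	TIME OBSERVATIONS STARTED	DURATION MINUTES	EFFORT DISTANCE KM	NUMBER OBSERVERS	PROTOCOL TYPE	ALL SPECIES REPORTED
F001	spfix	2	0.10	0.10	2015-06-01	07:30:00	60	0	1	Stationary	1
F002	spfix	1	0.20	0.20	2016-03-12	08:00:00	300	0	2	Stationary	1
F003	spfix	X	0.30	0.30	2018-09-05	06:45:00	45	2.5	1	Traveling	1
F004	spfix	3	0.40	0.40	2010-01-01	09:15:00	120	5.0	1	Traveling	1
F005	spfix	1	0.50	0.50	2021-06-30	16:00:00	90	1.2	3	Traveling	1
F006	spfix	4	0.60	0.60	2019-11-23	07:00:00	20	0	1	Birdlife Australia 20min-2ha survey	1
F007	spfix	1	0.15	0.25	2015-06-02	07:30:00	60	0	1	Stationary	0
F008	spfix	2	0.25	0.35	2015-06-03	07:30:00	60	0	1	Incidental	1
F009	spfix	1	0.35	0.45	2015-06-04	07:30:00	301	0	1	Stationary	1
F010	spfix	1	0.45	0.55	2015-06-05	07:30:00	60	5.1	1	Traveling	1
F011	spfix	2	0.55	0.65	2022-01-15	07:30:00	60	0	1	Stationary	1
F012	spfix	1	9.50	9.50	2015-06-06	07:30:00	60	0	1	Stationary	1
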