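2010-11-04 00:01:00 M001 ON
2010-11-04 00:01:05 M001 OFF
2010-11-04 00:03:00 M013 ON Meal_Preparation begin
2010-11-04 00:03:10 M013 OFF
2010-11-04 00:03:20 M014 ON
2010-11-04 00:03:30 M014 OFF
2010-11-04 00:04:00 M013 ON Meal_Preparation end
2010-11-04 00:10:00 M020 ON
2010-11-04 00:30:00 M003 ON Sleeping begin
2010-11-04 00:40:00 M003 OFF
2010-11-04 01:40:00 M002 ON
2010-11-04 01:41:00 M002 OFF Sleeping end
2010-11-04 02:00:00 D001 OPEN Leave_Home begin
2010-11-04 02:00:05 D001 CLOSE Leave_Home end
2010-11-04 02:30:00 M010 ON
2010-11-04 02:30:05 M010 OFF
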