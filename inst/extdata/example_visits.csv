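cat_id,sex,birth_date,visit_date,bodyweight_kg,visit_category,bcs_category,rolled_over,in_carrier,neuter_date,exclusion_diagnosis
cat00001,M,2007-03-13,2007-06-20,1.81436948004014,preventative,unknown,FALSE,FALSE,2007-07-23,FALSE
cat00001,M,2007-03-13,2008-03-04,4.57886622237704,other,normal,FALSE,FALSE,2007-07-23,FALSE
cat00001,M,2007-03-13,2008-06-23,4.55101917078582,preventative,unknown,FALSE,FALSE,2007-07-23,FALSE
cat00001,M,2007-03-13,2009-01-22,4.98951607011039,preventative,normal,FALSE,FALSE,2007-07-23,FALSE
cat00001,M,2007-03-13,2009-03-11,5.15473668272668,healthy_diagnosis,unknown,FALSE,FALSE,2007-07-23,FALSE
cat00002,M,2008-11-16,2009-01-24,0.969086240138866,preventative,unknown,FALSE,FALSE,,FALSE
cat00002,M,2008-11-16,2009-03-06,1.45826340827437,healthy_diagnosis,normal,FALSE,FALSE,,FALSE
cat00002,M,2008-11-16,2009-08-26,3.67688585521916,preventative,unknown,FALSE,FALSE,,FALSE
cat00002,M,2008-11-16,2009-11-07,3.75706766337551,preventative,normal,FALSE,FALSE,,FALSE
cat00003,M,2012-07-29,2012-09-27,1.06886098167082,preventative,normal,FALSE,FALSE,2012-12-08,FALSE
cat00003,M,2012-07-29,2012-10-17,1.40128035561451,preventative,normal,FALSE,FALSE,2012-12-08,FALSE
cat00003,M,2012-07-29,2013-07-06,3.50994586635205,preventative,unknown,FALSE,FALSE,2012-12-08,FALSE
cat00003,M,2012-07-29,2014-03-28,4.40295863128975,preventative,normal,FALSE,FALSE,2012-12-08,FALSE
cat00003,M,2012-07-29,2014-12-01,4.15451697507308,preventative,unknown,FALSE,FALSE,2012-12-08,FALSE
cat00004,F,2011-11-25,2012-01-24,1.06139608952216,preventative,normal,FALSE,FALSE,2012-06-10,FALSE
cat00004,F,2011-11-25,2012-01-27,1.13267921395273,other,unknown,FALSE,FALSE,2012-06-10,FALSE
cat00004,F,2011-11-25,2012-01-29,1.1164558223237,preventative,normal,FALSE,FALSE,2012-06-10,FALSE
cat00004,F,2011-11-25,2012-02-02,1.25262868770891,preventative,unknown,FALSE,FALSE,2012-06-10,FALSE
cat00004,F,2011-11-25,2012-08-02,2.72155422006021,preventative,normal,FALSE,FALSE,2012-06-10,FALSE
cat00005,M,2006-07-02,2006-09-22,1.38694926200593,preventative,normal,FALSE,FALSE,2006-11-03,FALSE
cat00005,M,2006-07-02,2006-10-08,1.54656913573553,preventative,normal,FALSE,FALSE,2006-11-03,FALSE
cat00005,M,2006-07-02,2007-07-08,4.02561230599963,preventative,normal,FALSE,FALSE,2006-11-03,FALSE
cat00006,F,2007-10-08,2007-11-21,0.840126660602298,preventative,normal,FALSE,FALSE,2008-01-13,FALSE
cat00006,F,2007-10-08,2007-12-28,1.16833748863279,preventative,normal,FALSE,FALSE,2008-01-13,FALSE
cat00006,F,2007-10-08,2007-12-29,1.15996370629675,other,unknown,FALSE,FALSE,2008-01-13,FALSE
cat00006,F,2007-10-08,2008-01-21,1.81436948004014,preventative,normal,FALSE,FALSE,2008-01-13,FALSE
cat00006,F,2007-10-08,2008-10-02,3.56218781435259,preventative,unknown,FALSE,FALSE,2008-01-13,FALSE
cat00006,F,2007-10-08,2009-12-20,4.3518595063716,preventative,normal,FALSE,FALSE,2008-01-13,FALSE
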