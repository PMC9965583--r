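patient_id,age,gender,disease,drug_name,dose_amount,dose_unit,dose_frequency,therapy_start,event_date,outcome_codes
P001,58,Male,Osteoporosis,Evista,60,milligram,Every day,2011-01-27,2011-11-03,other;disability
P002,82,Female,Osteoporosis prophylaxis,Evista,20,milligram,Every week,2012-07-14,2016-07-31,required intervention;life-threatening
P003,53,Female,Osteoporosis,Fosamax,60,milligram,Every day,2011-11-30,2014-03-26,life-threatening
P004,68,Female,Osteoporosis,Prolia,60,milligram,Every month,2011-05-31,2013-01-28,disability;required intervention
P005,86,Female,Osteoporosis,Fosamax,60,milligram,Every week,2014-03-18,2018-02-05,hospitalization
P006,60,Female,Osteoporosis,Fosamax,20,milligram,Every week,2011-05-25,2014-03-20,death;life-threatening
P007,62,Male,Osteoporosis,Prolia,60,milligram,Every day,2010-11-13,2014-03-18,life-threatening
P008,60,Female,Osteoporosis,Prolia,5,microgram,Every month,2014-09-20,2016-12-11,death;other
P009,64,Female,Osteoporosis,Forteo,20,microgram,Every month,2012-09-24,2013-12-09,required intervention;hospitalization
P010,69,Female,Osteoporosis,Fosamax,70,microgram,Every month,2011-11-07,2012-08-27,death;life-threatening
P011,81,Female,Osteoporosis,Evista,70,milligram,Every month,2012-09-27,2016-06-03,life-threatening;disability
P012,58,Female,Osteoporosis,Fosamax,20,microgram,Every day,2012-12-11,2013-09-01,other
P013,55,Female,Osteoporosis,Evista,20,milligram,Every week,2014-03-15,2016-06-15,disability;life-threatening
P014,65,Female,Osteoporosis,Evista,5,milligram,Every day,2011-12-25,2015-03-12,disability
P015,55,Female,Osteoporosis,Fosamax,20,milligram,Every day,2010-03-13,2013-08-19,required intervention;life-threatening
P016,65,Female,Osteoporosis,Prolia,60,milligram,Every day,2015-02-26,2019-02-09,disability;other
P017,60,Female,Osteoporosis,Forteo,60,milligram,Every week,2012-03-24,2012-11-09,required intervention;hospitalization
P018,43,Female,Osteoporosis,Forteo,70,milligram,Every week,2013-09-26,2016-11-22,life-threatening
P019,70,Female,Osteoporosis,Evista,5,milligram,Every day,2014-08-25,2017-02-09,life-threatening;disability
P020,64,Female,Osteoporosis,Fosamax,20,microgram,Every month,2011-05-31,2014-11-15,disability;hospitalization
P021,77,Male,Osteoporosis,Prolia,5,microgram,Every month,2012-08-24,2014-05-23,disability;death
P022,77,Female,Osteoporosis,Prolia,20,microgram,Every week,2012-08-26,2013-04-10,required intervention
P023,83,Female,Osteoporosis,Prolia,20,microgram,Every week,2011-07-18,2015-02-14,required intervention
P024,75,Male,Osteoporosis,Prolia,20,microgram,Every week,2010-07-02,2012-07-28,life-threatening
P025,76,Female,Osteoporosis,Forteo,5,microgram,Every month,2013-01-25,2013-05-03,required intervention;disability
P026,64,Female,Osteoporosis,Prolia,60,microgram,Every week,2010-07-02,2013-10-18,other
P027,83,Female,Osteoporosis,Prolia,60,microgram,Every month,2010-11-29,2012-04-07,hospitalization;death
P028,83,Female,Osteoporosis,Prolia,5,milligram,Every month,2011-08-09,2014-07-06,hospitalization
P029,60,Female,Osteoporosis,Prolia,20,milligram,Every day,2010-10-26,2011-05-25,hospitalization
P030,58,Female,Osteoporosis,Prolia,5,microgram,Every month,2011-06-23,2014-07-27,disability;hospitalization
P031,70,Female,Osteoporosis,Forteo,60,microgram,Every month,2013-02-16,2014-12-18,other
P032,79,Female,Osteoporosis,Prolia,5,milligram,Every day,2011-10-03,2013-05-12,death;life-threatening
P033,91,Female,Osteoporosis,Forteo,5,microgram,Every week,2011-05-23,2013-02-07,life-threatening
P034,80,Female,Osteoporosis,Evista,60,microgram,Every month,2012-04-01,2013-02-19,life-threatening
P035,83,Female,Osteoporosis,Prolia,60,microgram,Every day,2014-08-26,2014-09-19,other;disability
P036,77,Female,Osteoporosis,Prolia,70,microgram,Every month,2012-03-19,2013-02-24,other;hospitalization
P037,56,Female,Osteoporosis,Fosamax,5,milligram,Every day,2012-12-29,2015-09-03,required intervention
P038,45,Female,Osteoporosis,Fosamax,20,microgram,Every month,2010-03-14,2013-08-25,death
P039,48,Female,Osteoporosis,Prolia,70,microgram,Every month,2015-01-30,2015-08-23,disability;other
P040,65,Female,Osteoporosis,Forteo,70,milligram,Every week,2012-05-29,2014-04-30,life-threatening;disability
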