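ptt,deployed,last_message,tracking_days,total_locs,locs_per_day,deviance,dic,analyzed
829,2001-03-26,2001-04-30,35,8,1.2,-184,-179,TRUE
830,2001-03-31,2001-05-27,57,32,1.3,-64.3,-19.7,TRUE
849,2001-03-30,2001-09-22,176,242,1.9,-1176,-922,TRUE
824,2001-03-31,2001-04-20,20,51,2.6,-51.4,-20.1,TRUE
833,2001-03-27,2001-04-28,32,78,2.6,-188,-139,TRUE
834,2001-03-22,2001-04-11,20,13,1.1,-111,-79.5,TRUE
836,2001-03-26,2001-08-26,153,50,1.1,62.92,126.1,TRUE
840,2001-03-26,2001-08-05,10,5,NA,NA,NA,FALSE
843,2001-03-26,2001-04-21,26,31,2.1,-143,-111,TRUE
23033,2001-03-31,2001-04-10,10,0,NA,NA,NA,FALSE
23038,2001-03-27,2001-07-23,118,96,1.5,-542,-390,TRUE
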