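item_id,mean,c1,frac_high,c2,frac_low,c3,obs_min,obs_max,c4,frac_upsetting,c5,frac_difficult,c6,completion,c7,frac_priority,c8,screen_keep,action,resulting_items,rationale
s01,1.8,1,0.23,0,0.77,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,DELETE,0,symptom is rare
s02,2.0,1,0.30,0,0.70,1,1,4,1,0.00,1,0.05,0,1.00,1,0.00,0,1,DELETE,0,symptom is rare and some patients did not understand it
s03,2.9,1,0.66,1,0.34,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,DELETE,0,too similar to s06
s04,2.7,1,0.57,1,0.43,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s05,2.1,1,0.34,0,0.66,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s06,2.9,1,0.64,1,0.36,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s07,2.4,1,0.38,0,0.62,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s08,2.1,1,0.34,0,0.62,1,1,4,1,0.00,1,0.07,0,0.96,1,0.00,0,1,KEEP,1,
s09,2.1,1,0.36,0,0.64,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s10,2.1,1,0.30,0,0.70,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s11,1.7,1,0.21,0,0.79,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s12,1.9,1,0.23,0,0.77,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s13,1.8,1,0.26,0,0.74,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,CHANGE,1,have you experienced problems with swelling or inflammation in your mouth?
s14,2.1,1,0.34,0,0.66,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s15,2.4,1,0.43,0,0.57,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s16,2.5,1,0.51,1,0.43,1,1,4,1,0.00,1,0.00,1,0.94,0,0.00,0,1,DELETE,0,"applicable only to few patients, better in s26"
s17,1.9,1,0.30,0,0.70,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s18,2.3,1,0.36,0,0.64,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s19,1.6,1,0.17,0,0.83,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s20,1.9,1,0.23,0,0.74,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s21,2.2,1,0.36,0,0.60,1,1,4,1,0.00,1,0.07,0,0.96,1,0.02,1,1,DELETE,0,difficult to understand and the issue is covered in other items
s22,2.3,1,0.40,0,0.60,1,1,4,1,0.00,1,0.00,1,1.00,1,0.02,1,1,KEEP,1,
s23,2.1,1,0.32,0,0.64,1,1,4,1,0.00,1,0.02,1,0.96,1,0.00,0,1,KEEP,1,
s24,2.3,1,0.40,0,0.57,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s25,3.1,1,0.79,1,0.19,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,KEEP,1,
s26,1.9,1,0.21,0,0.68,1,1,4,1,0.00,1,0.00,1,0.89,0,0.00,0,1,KEEP,1,
s27,3.1,1,0.72,1,0.21,1,1,4,1,0.00,1,0.00,1,0.94,0,0.05,1,1,CHANGE,1,change of time frame (0.5 year)
s28,2.6,1,0.47,0,0.45,1,1,4,1,0.00,1,0.00,1,0.91,0,0.05,1,1,KEEP,1,
s29,2.2,1,0.36,0,0.62,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s30,2.2,1,0.36,0,0.62,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,KEEP,1,
s31,2.2,1,0.36,0,0.60,1,1,4,1,0.00,1,0.07,0,0.96,1,0.00,0,1,DELETE,0,too similar to s30
s32,2.3,1,0.38,0,0.60,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,KEEP,1,
s33,2.3,1,0.40,0,0.51,1,1,4,1,0.00,1,0.02,1,0.91,0,0.00,0,1,KEEP,1,
s34,2.6,1,0.47,0,0.38,1,1,4,1,0.00,1,0.05,0,0.85,0,0.00,0,0,DELETE,0,difficult to understand and too similar to s33
s35,2.3,1,0.36,0,0.62,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s36,2.2,1,0.32,0,0.66,1,1,4,1,0.02,1,0.00,1,0.98,1,0.02,1,1,KEEP,1,
s37,2.4,1,0.40,0,0.55,1,1,4,1,0.00,1,0.00,1,0.96,1,0.00,0,1,KEEP,1,
s38,2.3,1,0.38,0,0.57,1,1,4,1,0.00,1,0.00,1,0.96,1,0.05,1,1,DELETE,0,better in s37
s39,2.5,1,0.47,0,0.51,1,1,4,1,0.02,1,0.00,1,0.98,1,0.02,1,1,DELETE,0,better in s40
s40,2.6,1,0.47,0,0.47,1,1,4,1,0.02,1,0.02,1,0.94,0,0.02,1,1,KEEP,1,
s41,2.4,1,0.45,0,0.53,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,DELETE,0,not sensitive to change and better covered by other items
s42,2.2,1,0.34,0,0.62,1,1,4,1,0.00,1,0.00,1,0.96,1,0.02,1,1,KEEP,1,
s43,2.4,1,0.51,1,0.47,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,KEEP,1,
s44,2.3,1,0.45,0,0.53,1,1,4,1,0.00,1,0.02,1,0.98,1,0.02,1,1,DELETE,0,not clear enough
s45,2.6,1,0.60,1,0.40,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,DELETE,0,too similar to s46
s46,2.3,1,0.49,0,0.51,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,CHANGE,1,did you feel supported by friends and family?
s47,2.7,1,0.51,1,0.47,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s48,2.9,1,0.64,1,0.34,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s49,2.4,1,0.49,0,0.51,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s50,1.9,1,0.13,0,0.70,1,1,4,1,0.00,1,0.07,0,0.83,0,0.00,0,0,DELETE,0,relevance differs per patient
s51,2.3,1,0.38,0,0.62,1,1,4,1,0.00,1,0.00,1,1.00,1,0.02,1,1,KEEP,1,
s52,2.3,1,0.38,0,0.51,1,1,4,1,0.00,1,0.00,1,0.89,0,0.02,1,1,KEEP,1,
s53,2.8,1,0.62,1,0.38,1,1,4,1,0.00,1,0.00,1,1.00,1,0.02,1,1,KEEP,1,
s54,2.5,1,0.51,1,0.49,1,1,4,1,0.00,1,0.00,1,1.00,1,0.02,1,1,KEEP,1,
s55,2.5,1,0.51,1,0.49,1,1,4,1,0.00,1,0.00,1,1.00,1,0.02,1,1,KEEP,1,
s56,2.4,1,0.43,0,0.55,1,1,4,1,0.00,1,0.00,1,0.98,1,0.02,1,1,CHANGE,1,have you been concerned that there would be no more viable treatment for you?
s57,2.5,1,0.43,0,0.45,1,1,4,1,0.02,1,0.00,1,0.87,0,0.02,1,1,DELETE,0,too many missing; applicable only to few patients
s58,2.8,1,0.60,1,0.38,1,1,4,1,0.00,1,0.00,1,0.98,1,0.05,1,1,KEEP,1,
s59,2.4,1,0.45,0,0.55,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s60,2.2,1,0.40,0,0.57,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s61,2.4,1,0.40,0,0.55,1,1,4,1,0.00,1,0.00,1,0.96,1,0.00,0,1,KEEP,1,
s62,2.6,1,0.47,0,0.51,1,1,4,1,0.02,1,0.00,1,0.98,1,0.00,0,1,DELETE,0,too similar to other items
s63,2.8,1,0.62,1,0.38,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s64,2.4,1,0.45,0,0.55,1,1,4,1,0.00,1,0.00,1,1.00,1,0.00,0,1,KEEP,1,
s65,2.0,1,0.32,0,0.66,1,1,4,1,0.00,1,0.02,1,0.98,1,0.00,0,1,KEEP,1,
s66,2.9,1,0.70,1,0.28,1,1,4,1,0.00,1,0.00,1,0.98,1,0.00,0,1,KEEP,1,
s67,3.4,1,0.83,1,0.13,1,1,4,1,0.00,1,0.02,1,0.96,1,0.00,0,1,DELETE,0,better in s63
s68,2.5,1,0.38,0,0.30,1,1,4,1,0.00,1,0.00,1,0.68,0,0.00,0,1,CHANGE,1,did you miss interaction with other patients? (time frame: 0.5 year)
s69,2.2,1,0.15,0,0.28,1,1,4,1,0.05,1,0.02,1,0.43,0,0.00,0,1,EXPAND,2,have you had less interest in sexuality? could you enjoy sexuality less?
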