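etype,intervention,window,group,n,mean,sd
vpb,first_ligation,0-12h,URI,9,60.1,42.19
vpb,first_ligation,0-12h,SRI,6,47.5,25.8
vpb,first_ligation,0-12h,MIC,6,259.0,457.69
vpb,first_ligation,0-15min,URI,9,1.8,4.25
vpb,first_ligation,0-15min,SRI,6,2.0,3.63
vpb,first_ligation,0-15min,MIC,6,7.5,14.08
vpb,first_ligation,15-45min,URI,9,3.6,4.30
vpb,first_ligation,15-45min,SRI,6,3.0,4.69
vpb,first_ligation,15-45min,MIC,6,4.6,5.57
vpb,first_ligation,45min-12h,URI,9,54.5,39.85
vpb,first_ligation,45min-12h,SRI,6,42.5,27.38
vpb,first_ligation,45min-12h,MIC,6,246.8,440.84
vpb,second_ligation,0-12h,URI,9,1105.0,1146.72
vpb,second_ligation,0-12h,SRI,6,178.16,370.12
vpb,second_ligation,0-12h,MIC,6,7.5,8.98
vpb,second_ligation,0-15min,URI,9,7.1,7.97
vpb,second_ligation,0-15min,SRI,6,4.0,4.04
vpb,second_ligation,0-15min,MIC,6,0.3,0.81
vpb,second_ligation,15-45min,URI,9,15.6,22.75
vpb,second_ligation,15-45min,SRI,6,0.33,0.51
vpb,second_ligation,15-45min,MIC,6,3.8,7.22
vpb,second_ligation,45min-12h,URI,9,1082.2,1127.77
vpb,second_ligation,45min-12h,SRI,6,173.8,371.56
vpb,second_ligation,45min-12h,MIC,6,3.3,2.42
bg_tg,first_ligation,0-12h,URI,9,1.1,1.45
bg_tg,first_ligation,0-12h,SRI,6,3.66,4.17
bg_tg,first_ligation,0-12h,MIC,6,23.6,49.35
bg_tg,first_ligation,0-15min,URI,9,0,0
bg_tg,first_ligation,0-15min,SRI,6,0.16,0.40
bg_tg,first_ligation,0-15min,MIC,6,1.3,3.26
bg_tg,first_ligation,15-45min,URI,9,0.1,0.33
bg_tg,first_ligation,15-45min,SRI,6,0.16,0.40
bg_tg,first_ligation,15-45min,MIC,6,0.6,1.21
bg_tg,first_ligation,45min-12h,URI,9,1.0,1.50
bg_tg,first_ligation,45min-12h,SRI,6,3.33,4.32
bg_tg,first_ligation,45min-12h,MIC,6,21.6,45.89
bg_tg,second_ligation,0-12h,URI,9,113.8,146.02
bg_tg,second_ligation,0-12h,SRI,6,9.5,18.41
bg_tg,second_ligation,0-12h,MIC,6,0,0
bg_tg,second_ligation,0-15min,URI,9,0.5,0.72
bg_tg,second_ligation,0-15min,SRI,6,0,0
bg_tg,second_ligation,0-15min,MIC,6,0,0
bg_tg,second_ligation,15-45min,URI,9,0.6,1.65
bg_tg,second_ligation,15-45min,SRI,6,0,0
bg_tg,second_ligation,15-45min,MIC,6,0,0
bg_tg,second_ligation,45min-12h,URI,9,112.6,144.78
bg_tg,second_ligation,45min-12h,SRI,6,9.5,18.41
bg_tg,second_ligation,45min-12h,MIC,6,0,0
salvo,first_ligation,0-12h,URI,9,9.0,9.89
salvo,first_ligation,0-12h,SRI,6,3.5,3.27
salvo,first_ligation,0-12h,MIC,6,25.3,29.96
salvo,first_ligation,0-15min,URI,9,0,0
salvo,first_ligation,0-15min,SRI,6,1.16,1.83
salvo,first_ligation,0-15min,MIC,6,1.0,1.54
salvo,first_ligation,15-45min,URI,9,0.5,0.88
salvo,first_ligation,15-45min,SRI,6,0.5,0.54
salvo,first_ligation,15-45min,MIC,6,12.1,0.64
salvo,first_ligation,45min-12h,URI,9,8.4,10.17
salvo,first_ligation,45min-12h,SRI,6,1.83,2.56
salvo,first_ligation,45min-12h,MIC,6,12.1,18.17
salvo,second_ligation,0-12h,URI,9,201.7,296.77
salvo,second_ligation,0-12h,SRI,6,1.0,1.67
salvo,second_ligation,0-12h,MIC,6,0.5,0.83
salvo,second_ligation,0-15min,URI,9,0.3,0.50
salvo,second_ligation,0-15min,SRI,6,1.0,1.67
salvo,second_ligation,0-15min,MIC,6,0,0
salvo,second_ligation,15-45min,URI,9,0,0
salvo,second_ligation,15-45min,SRI,6,0,0
salvo,second_ligation,15-45min,MIC,6,0.5,0.83
salvo,second_ligation,45min-12h,URI,9,201.4,296.89
salvo,second_ligation,45min-12h,SRI,6,0,0
salvo,second_ligation,45min-12h,MIC,6,0,0
vt,first_ligation,0-12h,URI,9,1.3,2.69
vt,first_ligation,0-12h,SRI,6,0.66,0.51
vt,first_ligation,0-12h,MIC,6,4.1,3.97
vt,first_ligation,0-15min,URI,9,0.5,0.83
vt,first_ligation,0-15min,SRI,6,0.16,0.40
vt,first_ligation,0-15min,MIC,6,0,0
vt,first_ligation,15-45min,URI,9,0.3,1.00
vt,first_ligation,15-45min,SRI,6,0.16,0.40
vt,first_ligation,15-45min,MIC,6,2.0,4.42
vt,first_ligation,45min-12h,URI,9,1.0,2.64
vt,first_ligation,45min-12h,SRI,6,0.33,0.51
vt,first_ligation,45min-12h,MIC,6,1.6,1.86
vt,second_ligation,0-12h,URI,9,32.6,52.51
vt,second_ligation,0-12h,SRI,6,1.0,1.26
vt,second_ligation,0-12h,MIC,6,0,0
vt,second_ligation,0-15min,URI,9,0,0
vt,second_ligation,0-15min,SRI,6,0.83,1.16
vt,second_ligation,0-15min,MIC,6,0,0
vt,second_ligation,15-45min,URI,9,0,0
vt,second_ligation,15-45min,SRI,6,0.16,0.40
vt,second_ligation,15-45min,MIC,6,0,0
vt,second_ligation,45min-12h,URI,9,32.6,52.51
vt,second_ligation,45min-12h,SRI,6,0,0
vt,second_ligation,45min-12h,MIC,6,0,0
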