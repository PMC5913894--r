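block,priority,volume,type,goal,parameters
constraint,NA,PTV,maximum,105% of Dp,
constraint,NA,PTV Shell 39 mm,maximum,50% of Dp,
constraint,NA,Body,maximum,105% of Dp,
objective,1,PTV,LTCP,0.4,"Dp = 45 Gy, alpha = 4"
objective,2,PTV Shell 3 mm,maximum,90% of Dp,
objective,3,Kidneys,mean,8 Gy,
objective,4,Liver,mean,15 Gy,
objective,5,Heart,EUD,15 Gy,k = 6
objective,6,SpinalCord,EUD,25 Gy,k = 12
objective,7,PTV Shell 18 mm,maximum,40% of Dp,
objective,7,SkinRing,maximum,25% of Dp,
objective,8,Kidneys,dose-volume,25%,threshold = 12 Gy
objective,8,Liver,dose-volume,30%,threshold = 24 Gy
objective,9,Lungs,dose-volume,50%,threshold = 20 Gy
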