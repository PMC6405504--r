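species,ssdi_printed,mean_printed
Austroplebeia australis,0.091,1.37
Austroplebeia cassiae,0.058,1.41
Austroplebeia cincta,0.070,1.19
Austroplebeia essingtoni,0.035,1.15
Austroplebeia magna,0.030,1.37
Axestotrigona ferruginea,0.160,2.16
Bombus terrestris,0.013,7.81
Cephalotrigona capitata,0.425,3.19
Cephalotrigona zexmeniae,0.282,2.196
Euglossa imperialis,0.043,5.50
Exaerete smaragdina,0.150,7.58
Frieseomelitta nigra,0.034,1.329
Lepidotrigona ventralis,0.385,1.765
Lestrimelitta limao,0.375,2.375
Lestrimelitta niitkib,0.191,1.737
Melipona beecheii,-0.155,2.357
Melipona bicolor,-0.188,3.625
Melipona colimana,-0.095,2.842
Melipona eburnea,-0.063,4.558
Melipona fallax,-0.014,3.51
Melipona favosa,-0.264,2.321
Melipona fuliginosa,-0.151,3.625
Melipona marginata,-0.193,2.083
Melipona quadrifasciata,-0.095,2.747
Melipona rufiventris,-0.188,3.63
Melipona scutellaris,-0.056,2.79
Melipona yucatanica,-0.11,2.107
Nannotrigona perilampoides,0.187,1.338
Oxytrigona tataira,0.424,1.841
Partamona bilineata,0.060,1.608
Plebeia frontalis,-0.024,1.00
Scaptotrigona mexicana,0.194,1.672
Scaptotrigona pectoralis,0.157,1.706
Scaura latitarsis,0.200,1.375
Scaura longula,0.107,1.58
Schwarziana quadripunctata,0.093,1.952
Tetragonisca angustula,0.777,1.473
Trichotrigona extranea,-0.155,1.365
Trigona amalthea,0.376,2.355
Trigona chanchamayoensis,0.375,2.375
Trigona corvina,0.222,2.50
Trigona fulviventris,0.165,1.738
Trigona nigerrima,0.100,2.625
Trigona pallens,0.188,1.884
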