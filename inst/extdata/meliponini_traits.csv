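species,worker_mm,male_mm,queen_mm,genus,source
Austroplebeia australis,1.31,1.31,1.43,Austroplebeia,d
Austroplebeia cassiae,1.36,1.37,1.45,Austroplebeia,d
Austroplebeia cincta,1.11,1.15,1.23,Austroplebeia,d
Austroplebeia essingtoni,1.10,1.13,1.17,Austroplebeia,d
Austroplebeia magna,1.33,1.35,1.39,Austroplebeia,d
Axestotrigona ferruginea,1.925,2.00,2.32,Axestotrigona,c
Bombus terrestris,4.77,7.76,7.86,Bombus,k
Cephalotrigona capitata,2.88,2.63,3.75,Cephalotrigona,b
Cephalotrigona zexmeniae,2.081,1.925,2.468,Cephalotrigona,m
Euglossa imperialis,,5.38,5.61,Euglossa,n
Exaerete smaragdina,,7.05,8.11,Exaerete,n
Frieseomelitta nigra,1.227,1.307,1.352,Frieseomelitta,m
Lepidotrigona ventralis,1.44,1.48,2.05,Lepidotrigona,f
Lestrimelitta limao,2.00,2.00,2.75,Lestrimelitta,b
Lestrimelitta niitkib,1.493,1.584,1.89,Lestrimelitta,m
Melipona beecheii,2.528,2.556,2.158,Melipona,l
Melipona bicolor,3.875,4.00,3.25,Melipona,b
Melipona colimana,2.894,2.985,2.699,Melipona,m
Melipona eburnea,4.89,4.708,4.409,Melipona,e
Melipona fallax,3.43,3.53,3.48,Melipona,h
Melipona favosa,2.633,2.675,1.968,Melipona,i
Melipona fuliginosa,3.68,3.92,3.33,Melipona,h
Melipona marginata,2.299,2.307,1.86,Melipona,i
Melipona quadrifasciata,2.888,2.884,2.61,Melipona,i
Melipona rufiventris,3.75,4.00,3.25,Melipona,a
Melipona scutellaris,3.01,2.87,2.71,Melipona,j
Melipona yucatanica,2.235,2.245,1.97,Melipona,m
Nannotrigona perilampoides,1.309,1.224,1.453,Nannotrigona,m
Oxytrigona tataira,1.526,1.522,2.16,Oxytrigona,i
Partamona bilineata,1.589,1.561,1.655,Partamona,m
Plebeia frontalis,1.02,1.018,0.993,Plebeia,m
Scaptotrigona mexicana,1.453,1.524,1.82,Scaptotrigona,m
Scaptotrigona pectoralis,1.613,1.582,1.831,Scaptotrigona,m
Scaura latitarsis,1.25,1.25,1.50,Scaura,b
Scaura longula,1.50,1.50,1.66,Scaura,b
Schwarziana quadripunctata,1.748,1.865,2.039,Schwarziana,i
Tetragonisca angustula,1.019,1.061,1.886,Tetragonisca,e
Trichotrigona extranea,NA,1.48,1.25,Trichotrigona,g
Trigona amalthea,2.218,1.982,2.729,Trigona,e
Trigona chanchamayoensis,1.88,2.00,2.75,Trigona,b
Trigona corvina,2.13,2.25,2.75,Trigona,b
Trigona fulviventris,1.429,1.606,1.871,Trigona,m
Trigona nigerrima,2.38,2.50,2.75,Trigona,b
Trigona pallens,1.416,1.722,2.047,Trigona,i
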