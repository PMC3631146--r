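patient_id,timepoint,site,log10_cfu,gi,pd
P001,T0,BRACKET_AREA,8.654580706595551,0.07578517931132867,0.7116344981062646
P001,T1,BO,9.036274930920698,0.6306813391921362,0.41818382121424724
P001,T1,BG,9.34347929863648,0.6306813391921362,0.41818382121424724
P001,T1,BL,9.045938956178356,0.6306813391921362,0.41818382121424724
P001,T1,BR,9.0404942902052845,0.6306813391921362,0.41818382121424724
P001,T2,BO,9.026773356072685,0.7674631663002287,0.43635441098439465
P001,T2,BG,9.425382064314578,0.7674631663002287,0.43635441098439465
P001,T2,BL,9.394475616621973,0.7674631663002287,0.43635441098439465
P001,T2,BR,9.388120652418808,0.7674631663002287,0.43635441098439465
P002,T0,BRACKET_AREA,8.628982354350388,0.4153488796095406,0.5607830522877577
P002,T1,BO,9.024733775409745,0.3936140656891732,0.5419385639204505
P002,T1,BG,9.338509686950738,0.3936140656891732,0.5419385639204505
P002,T1,BL,9.022093970509264,0.3936140656891732,0.5419385639204505
P002,T1,BR,9.020581765867817,0.3936140656891732,0.5419385639204505
P002,T2,BO,9.025328434955558,0.21404347595351436,0.7790854078977375
P002,T2,BG,9.377772663420888,0.21404347595351436,0.7790854078977375
P002,T2,BL,9.36727092565034,0.21404347595351436,0.7790854078977375
P002,T2,BR,9.399132127081344,0.21404347595351436,0.7790854078977375
P003,T0,BRACKET_AREA,8.64845797600952,0.4920014736634516,0.6003287697439366
P003,T1,BO,9.035784548369048,0.8205308612877855,0.3738094088926873
P003,T1,BG,9.341774596665301,0.8205308612877855,0.3738094088926873
P003,T1,BL,9.03118015321238,0.8205308612877855,0.3738094088926873
P003,T1,BR,9.053376048901503,0.8205308612877855,0.3738094088926873
P003,T2,BO,9.02643102617434,0.47750117750707366,0.7497199036146517
P003,T2,BG,9.40348446497955,0.47750117750707366,0.7497199036146517
P003,T2,BL,9.396926555053817,0.47750117750707366,0.7497199036146517
P003,T2,BR,9.38004993957526,0.47750117750707366,0.7497199036146517
P004,T0,BRACKET_AREA,8.643778173673981,0,0.5089160165241042
P004,T1,BO,9.044859725135394,0.16964688894618926,0.7555956315021173
P004,T1,BG,9.34205626387833,0.16964688894618926,0.7555956315021173
P004,T1,BL,9.040639948827684,0.16964688894618926,0.7555956315021173
P004,T1,BR,9.044251420624956,0.16964688894618926,0.7555956315021173
P004,T2,BO,9.02982871234413,0.42736319869093975,0.6972311980793
P004,T2,BG,9.416131621856179,0.42736319869093975,0.6972311980793
P004,T2,BL,9.407059573179094,0.42736319869093975,0.6972311980793
P004,T2,BR,9.392575886521005,0.42736319869093975,0.6972311980793
P005,T0,BRACKET_AREA,8.595307130168994,0.400769258594744,0.6706218088734648
P005,T1,BO,9.025204735161543,0.6032235990546739,0.6666204611686288
P005,T1,BG,9.334025107066699,0.6032235990546739,0.6666204611686288
P005,T1,BL,9.040358834567023,0.6032235990546739,0.6666204611686288
P005,T1,BR,9.0405640080160925,0.6032235990546739,0.6666204611686288
P005,T2,BO,9.039744214975276,0.44945175079869415,0.9217542244409357
P005,T2,BG,9.381957337067503,0.44945175079869415,0.9217542244409357
P005,T2,BL,9.410896217774054,0.44945175079869415,0.9217542244409357
P005,T2,BR,9.38348377487919,0.44945175079869415,0.9217542244409357
P006,T0,BRACKET_AREA,8.635816506978466,0.7740574204372916,0.23971961603804565
P006,T1,BO,9.037882745282511,0.38653039320399774,0.3180778884631848
P006,T1,BG,9.335808767208027,0.38653039320399774,0.3180778884631848
P006,T1,BL,9.03482776168102,0.38653039320399774,0.3180778884631848
P006,T1,BR,9.033897081542925,0.38653039320399774,0.3180778884631848
P006,T2,BO,9.032795431590129,1.0290507805841083,0.40620990015327824
P006,T2,BG,9.378698268565719,1.0290507805841083,0.40620990015327824
P006,T2,BL,9.402883056627969,1.0290507805841083,0.40620990015327824
P006,T2,BR,9.380953547978798,1.0290507805841083,0.40620990015327824
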