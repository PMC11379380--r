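id,group,gender,age_years,bmi,body_weight_kg,urine_conc_ug_per_L,urine_detect,urine_creatinine_mg_per_dL,hair_conc_ng_per_g,hair_detect
P001,polluted,male,46.13719788580257,27.906456676853743,76.23935560944366,15.317649035407308,1,298.73044743342865,4.544506522065201,1
P002,polluted,male,26.354841190552115,25.240019540592115,61.412567719207374,0.8223833912498452,1,177.39658951402646,3.669385457852844,1
P003,polluted,male,40.36559797397446,17.39208328098112,66.01056422488142,6.3606170732833,1,143.29792510332445,1.5682322333316763,0
P004,polluted,male,52.60694673670899,24.60239409000806,60.806126390675864,96.52552376285789,1,118.53916927522826,3.671135966149951,1
P005,polluted,female,34.98425780154482,20.124963624943188,55.24910166208952,27.344094001033156,1,138.90806812830607,6.335680974220997,1
P006,polluted,female,43.049439888378515,19.575085817031287,64.5819011539469,20.362757251435227,1,85.52521493800627,3.556682979370452,1
P007,polluted,female,51.59341091897272,29.009271561859087,56.679843227236994,45.58898328310628,1,89.07843896739895,2.410385922432589,1
P008,polluted,female,45.842599012486595,24.47558901570773,73.17837173448892,15.930046949061273,1,133.7256526583009,33.85898878002118,1
C001,control,male,53.69425152451141,28.34642078353218,57.39608921784923,0.5650192987293725,1,144.13898622403994,0.7050563059010393,1
C002,control,female,35.78855980670902,22.93675160815909,59.48321618510662,0.15715554934910356,0,77.27643053805693,0.5657401176205542,1
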