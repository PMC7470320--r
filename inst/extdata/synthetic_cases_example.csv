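"case_id","age","weight","height","body_mass_index","body_surface_area","aortic_annulus_diameter","aortic_annulus_area","aortic_valve_area","lvot_calcification","ilio_femoral_min_diameter_right","ilio_femoral_min_diameter_left","tortuosity_right","tortuosity_left","calcification_right","calcification_left","previous_aneurysm_or_thrombus","solution.vascular_access","solution.prosthesis","result.procedure_success"
"S001",80.86,74,164.93,27.04,1.8,26.03,500.48,0.8,"yes",5.2,5.19,"Moderate","Moderate","Moderate","Moderate","yes","left trans-subclavian","Medtronic CoreValve 29","yes"
"S002",80.98,73.86,165.31,26.99,1.8,26.04,500.28,0.8,"yes",6.8,8.49,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
"S003",80.92,74,165.12,27.05,1.8,23.51,420.59,0.75,"no",8.51,6.81,"No","Mild","No","Mild","no","right trans-femoral","Edwards Sapien XT 26","yes"
"S004",81.07,73.85,164.92,27,1.8,26.01,499.32,0.8,"yes",5.21,5.2,"Moderate","Moderate","Moderate","Moderate","yes","left trans-subclavian","Medtronic CoreValve 29","yes"
"S005",80.91,74.13,165.28,27.03,1.8,26,500.49,0.8,"yes",6.79,8.49,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
"S006",80.84,74.03,165.22,27.03,1.8,19.5,310.05,0.6,"no",6.8,8.51,"Mild","No","Mild","No","no","left trans-femoral","Edwards Sapien XT 23","yes"
"S007",81.14,74.14,164.82,27.02,1.8,26.01,500.26,0.8,"yes",6.8,8.51,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
"S008",81.09,74.07,165.21,26.96,1.8,23.48,419.41,0.75,"no",8.51,6.8,"No","Mild","No","Mild","no","right trans-femoral","Edwards Sapien XT 26","yes"
"S009",81.14,74.01,165.07,26.97,1.8,25.97,499.9,0.8,"yes",6.79,8.51,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
"S010",81.03,74.09,165.18,27.05,1.8,19.49,309.7,0.6,"no",6.81,8.51,"Mild","No","Mild","No","no","left trans-femoral","Edwards Sapien XT 23","yes"
"S011",80.86,73.87,165.02,26.96,1.8,26.02,500.77,0.8,"yes",6.8,8.49,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
"S012",81.05,73.95,164.71,26.99,1.8,26.01,499.71,0.8,"yes",6.8,8.49,"Mild","No","Mild","No","no","left trans-femoral","Medtronic CoreValve 29","yes"
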