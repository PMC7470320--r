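# Default TAVI case-base schema. Ordinal category labels are quoted so the
# YAML parser does not coerce 'No' into a boolean.
attributes:
  - {name: age, kind: quantitative, range: [40, 100]}
  - {name: weight, kind: quantitative, range: [35, 150]}
  - {name: height, kind: quantitative, range: [130, 200]}
  - {name: body_mass_index, kind: quantitative, range: [14, 50]}
  - {name: body_surface_area, kind: quantitative, range: [1.2, 2.6]}
  - {name: aortic_annulus_diameter, kind: quantitative, range: [15, 32]}
  - {name: aortic_annulus_area, kind: quantitative, range: [200, 800]}
  - {name: aortic_valve_area, kind: quantitative, range: [0.3, 1.5]}
  - {name: lvot_calcification, kind: binary}
  - {name: ilio_femoral_min_diameter_right, kind: quantitative, range: [3, 12]}
  - {name: ilio_femoral_min_diameter_left, kind: quantitative, range: [3, 12]}
  - {name: tortuosity_right, kind: ordinal, categories: ['No', 'Mild', 'Moderate', 'Severe']}
  - {name: tortuosity_left, kind: ordinal, categories: ['No', 'Mild', 'Moderate', 'Severe']}
  - {name: calcification_right, kind: ordinal, categories: ['No', 'Mild', 'Moderate', 'Heavy', 'Massive']}
  - {name: calcification_left, kind: ordinal, categories: ['No', 'Mild', 'Moderate', 'Heavy', 'Massive']}
  - {name: previous_aneurysm_or_thrombus, kind: binary}
decisions:
  vascular_access:
    - right trans-femoral
    - left trans-femoral
    - left trans-subclavian
    - trans-aortic
    - trans-apical
  prosthesis:
    - Edwards Sapien XT 23
    - Edwards Sapien XT 26
    - Medtronic CoreValve 26
    - Medtronic CoreValve 29
results: [procedure_success]
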