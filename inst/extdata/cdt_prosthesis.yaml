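# Clinical decision tree for the joint prosthesis type + size decision.
# Annulus dimensions and valve area dominate the size choice; the type is
# linked to the access route, hence the femoral attributes at level 2.
decision: prosthesis
levels:
  - [aortic_annulus_diameter, aortic_annulus_area, aortic_valve_area]
  - [lvot_calcification, ilio_femoral_min_diameter_right,
     ilio_femoral_min_diameter_left]
  - [age, body_surface_area]
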