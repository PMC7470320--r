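# Clinical decision tree for the vascular access decision. Artery calibre
# is examined first (trans-femoral access is preferred), then vessel
# quality and prior femoral disease, then patient build. Override per
# centre as local rules differ.
decision: vascular_access
levels:
  - [ilio_femoral_min_diameter_right, ilio_femoral_min_diameter_left]
  - [tortuosity_right, tortuosity_left, calcification_right, calcification_left,
     previous_aneurysm_or_thrombus]
  - [age, body_surface_area, body_mass_index]
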