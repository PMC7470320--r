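# Expert distance matrix for arterial calcification grades (example config;
# the same matrix ships in code as calcification_matrix()).
- attribute: calcification_right
  categories: ['No', 'Mild', 'Moderate', 'Heavy', 'Massive']
  matrix:
    - [0, 0.15, 0.5, 0.90, 1]
    - [0.15, 0, 0.2, 0.5, 0.7]
    - [0.5, 0.2, 0, 0.2, 0.5]
    - [0.90, 0.5, 0.2, 0, 0.15]
    - [1, 0.7, 0.5, 0.15, 0]
- attribute: calcification_left
  categories: ['No', 'Mild', 'Moderate', 'Heavy', 'Massive']
  matrix:
    - [0, 0.15, 0.5, 0.90, 1]
    - [0.15, 0, 0.2, 0.5, 0.7]
    - [0.5, 0.2, 0, 0.2, 0.5]
    - [0.90, 0.5, 0.2, 0, 0.15]
    - [1, 0.7, 0.5, 0.15, 0]
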