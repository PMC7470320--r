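# Solution-consistent measurement intervals per prosthesis, used by the
# data augmentation to keep generated annulus measurements coherent with
# the case's prosthesis. SYNTHETIC stand-in values modelled on typical
# device Instruction-For-Use sizing tables; edit to match the devices in
# use.
decision: prosthesis
ranges:
  Edwards Sapien XT 23:
    aortic_annulus_diameter: [18, 22]
    aortic_annulus_area: [280, 380]
  Edwards Sapien XT 26:
    aortic_annulus_diameter: [21, 25]
    aortic_annulus_area: [370, 480]
  Medtronic CoreValve 26:
    aortic_annulus_diameter: [20, 23]
    aortic_annulus_area: [310, 415]
  Medtronic CoreValve 29:
    aortic_annulus_diameter: [23, 27]
    aortic_annulus_area: [415, 572]
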