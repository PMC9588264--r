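# Named materials: component (water / trilysine / PEG / element symbol)
# weight fractions and mass density in g/cm3.
materials:
  iodinated_hydrogel:
    components: {water: 0.880, trilysine: 0.007, PEG: 0.101, I: 0.012}
    density: 1.03
  water:
    components: {water: 1.0}
    density: 1.00
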