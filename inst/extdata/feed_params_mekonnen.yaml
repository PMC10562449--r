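# Feed-conversion ratios, mekonnen source. The published tables give FCRs
# for grazing/mixed/industrial systems (industrial maps onto the canonical
# "intensive" class) but no crop-residue feed fractions; the loader
# therefore combines these FCRs with the herrero CRFF table (no crff block
# here on purpose). Plausible default magnitudes, replaceable by
# user-supplied tables.
fcr:
  - {region: any, animal_type: cattle, production_system: grazing, climate: any, product: meat, value: 1300}
  - {region: any, animal_type: cattle, production_system: mixed, climate: any, product: meat, value: 650}
  - {region: any, animal_type: cattle, production_system: intensive, climate: any, product: meat, value: 350}
  - {region: any, animal_type: cattle, production_system: other, climate: any, product: meat, value: 650}
  - {region: any, animal_type: cattle, production_system: grazing, climate: any, product: milk, value: 130}
  - {region: any, animal_type: cattle, production_system: any, climate: any, product: milk, value: 80}
  - {region: any, animal_type: sheep_goat, production_system: any, climate: any, product: meat, value: 1500}
  - {region: any, animal_type: sheep_goat, production_system: any, climate: any, product: milk, value: 150}
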