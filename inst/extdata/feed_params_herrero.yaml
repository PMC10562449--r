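# Herd-level feed-conversion ratios (kg dry-matter feed per kg protein)
# and crop-residue feed fractions, herrero source. Rows are matched by
# (region, animal_type, production_system, climate, product); "any" is a
# wildcard, and the most specific matching row wins. These defaults carry
# plausible magnitudes for the published regional tables and are meant to
# be replaced by user-supplied values for real-world work.
fcr:
  - {region: any, animal_type: cattle, production_system: grazing, climate: any, product: meat, value: 1500}
  - {region: any, animal_type: cattle, production_system: mixed, climate: any, product: meat, value: 700}
  - {region: any, animal_type: cattle, production_system: intensive, climate: any, product: meat, value: 400}
  - {region: any, animal_type: cattle, production_system: other, climate: any, product: meat, value: 700}
  - {region: any, animal_type: cattle, production_system: grazing, climate: any, product: milk, value: 150}
  - {region: any, animal_type: cattle, production_system: mixed, climate: any, product: milk, value: 90}
  - {region: any, animal_type: cattle, production_system: intensive, climate: any, product: milk, value: 60}
  - {region: any, animal_type: cattle, production_system: other, climate: any, product: milk, value: 90}
  - {region: any, animal_type: sheep_goat, production_system: grazing, climate: any, product: meat, value: 1800}
  - {region: any, animal_type: sheep_goat, production_system: mixed, climate: any, product: meat, value: 900}
  - {region: any, animal_type: sheep_goat, production_system: intensive, climate: any, product: meat, value: 500}
  - {region: any, animal_type: sheep_goat, production_system: other, climate: any, product: meat, value: 900}
  - {region: any, animal_type: sheep_goat, production_system: any, climate: any, product: milk, value: 140}
crff:
  - {region: any, animal_type: any, production_system: grazing, climate: any, product: any, value: 0.15}
  - {region: any, animal_type: any, production_system: mixed, climate: arid, product: any, value: 0.45}
  - {region: any, animal_type: any, production_system: mixed, climate: temperate, product: any, value: 0.25}
  - {region: any, animal_type: any, production_system: mixed, climate: tropical, product: any, value: 0.50}
  - {region: any, animal_type: any, production_system: intensive, climate: any, product: any, value: 0.10}
  - {region: any, animal_type: any, production_system: other, climate: any, product: any, value: 0.25}
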