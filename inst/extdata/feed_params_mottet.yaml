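# Feed-conversion ratios and crop-residue feed fractions, mottet source.
# The published tables distinguish only an OECD and a non-OECD region and
# the systems grazing/mixed/feedlot; feedlot maps onto the canonical
# "intensive" class. "any" rows are the non-OECD fallback. Plausible
# default magnitudes, replaceable by user-supplied tables.
fcr:
  - {region: oecd, animal_type: cattle, production_system: grazing, climate: any, product: meat, value: 1100}
  - {region: oecd, animal_type: cattle, production_system: mixed, climate: any, product: meat, value: 550}
  - {region: oecd, animal_type: cattle, production_system: intensive, climate: any, product: meat, value: 320}
  - {region: oecd, animal_type: cattle, production_system: any, climate: any, product: milk, value: 70}
  - {region: any, animal_type: cattle, production_system: grazing, climate: any, product: meat, value: 1700}
  - {region: any, animal_type: cattle, production_system: mixed, climate: any, product: meat, value: 850}
  - {region: any, animal_type: cattle, production_system: intensive, climate: any, product: meat, value: 450}
  - {region: any, animal_type: cattle, production_system: other, climate: any, product: meat, value: 850}
  - {region: any, animal_type: cattle, production_system: any, climate: any, product: milk, value: 110}
  - {region: any, animal_type: sheep_goat, production_system: any, climate: any, product: meat, value: 1100}
  - {region: any, animal_type: sheep_goat, production_system: any, climate: any, product: milk, value: 160}
crff:
  - {region: oecd, animal_type: any, production_system: any, climate: any, product: any, value: 0.08}
  - {region: any, animal_type: any, production_system: grazing, climate: any, product: any, value: 0.18}
  - {region: any, animal_type: any, production_system: mixed, climate: any, product: any, value: 0.40}
  - {region: any, animal_type: any, production_system: intensive, climate: any, product: any, value: 0.12}
  - {region: any, animal_type: any, production_system: other, climate: any, product: any, value: 0.25}
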