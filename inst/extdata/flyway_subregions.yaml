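# Default study region for the African-Eurasian flyway analysis:
# breeding-side Europe (Turkey included, Russia excluded) and nonbreeding-side
# sub-Saharan Africa (northern African countries excluded), grouped into four
# subregions per continent. This is overridable configuration, not code.
subregions:
  # --- Europe: western ---
  PRT: {continent: Europe, subregion: western Europe}
  ESP: {continent: Europe, subregion: western Europe}
  FRA: {continent: Europe, subregion: western Europe}
  BEL: {continent: Europe, subregion: western Europe}
  NLD: {continent: Europe, subregion: western Europe}
  LUX: {continent: Europe, subregion: western Europe}
  GBR: {continent: Europe, subregion: western Europe}
  IRL: {continent: Europe, subregion: western Europe}
  AND: {continent: Europe, subregion: western Europe}
  # --- Europe: central ---
  DEU: {continent: Europe, subregion: central Europe}
  CHE: {continent: Europe, subregion: central Europe}
  AUT: {continent: Europe, subregion: central Europe}
  CZE: {continent: Europe, subregion: central Europe}
  SVK: {continent: Europe, subregion: central Europe}
  POL: {continent: Europe, subregion: central Europe}
  HUN: {continent: Europe, subregion: central Europe}
  SVN: {continent: Europe, subregion: central Europe}
  ITA: {continent: Europe, subregion: central Europe}
  LIE: {continent: Europe, subregion: central Europe}
  # --- Europe: northern ---
  DNK: {continent: Europe, subregion: northern Europe}
  NOR: {continent: Europe, subregion: northern Europe}
  SWE: {continent: Europe, subregion: northern Europe}
  FIN: {continent: Europe, subregion: northern Europe}
  ISL: {continent: Europe, subregion: northern Europe}
  EST: {continent: Europe, subregion: northern Europe}
  LVA: {continent: Europe, subregion: northern Europe}
  LTU: {continent: Europe, subregion: northern Europe}
  # --- Europe: eastern ---
  BLR: {continent: Europe, subregion: eastern Europe}
  UKR: {continent: Europe, subregion: eastern Europe}
  MDA: {continent: Europe, subregion: eastern Europe}
  ROU: {continent: Europe, subregion: eastern Europe}
  BGR: {continent: Europe, subregion: eastern Europe}
  HRV: {continent: Europe, subregion: eastern Europe}
  BIH: {continent: Europe, subregion: eastern Europe}
  SRB: {continent: Europe, subregion: eastern Europe}
  MNE: {continent: Europe, subregion: eastern Europe}
  MKD: {continent: Europe, subregion: eastern Europe}
  ALB: {continent: Europe, subregion: eastern Europe}
  GRC: {continent: Europe, subregion: eastern Europe}
  CYP: {continent: Europe, subregion: eastern Europe}
  MLT: {continent: Europe, subregion: eastern Europe}
  TUR: {continent: Europe, subregion: eastern Europe}
  # --- Africa: western ---
  MRT: {continent: Africa, subregion: western Africa}
  SEN: {continent: Africa, subregion: western Africa}
  GMB: {continent: Africa, subregion: western Africa}
  GNB: {continent: Africa, subregion: western Africa}
  GIN: {continent: Africa, subregion: western Africa}
  SLE: {continent: Africa, subregion: western Africa}
  LBR: {continent: Africa, subregion: western Africa}
  CIV: {continent: Africa, subregion: western Africa}
  GHA: {continent: Africa, subregion: western Africa}
  TGO: {continent: Africa, subregion: western Africa}
  BEN: {continent: Africa, subregion: western Africa}
  NGA: {continent: Africa, subregion: western Africa}
  MLI: {continent: Africa, subregion: western Africa}
  BFA: {continent: Africa, subregion: western Africa}
  NER: {continent: Africa, subregion: western Africa}
  CPV: {continent: Africa, subregion: western Africa}
  # --- Africa: central ---
  TCD: {continent: Africa, subregion: central Africa}
  CMR: {continent: Africa, subregion: central Africa}
  CAF: {continent: Africa, subregion: central Africa}
  GNQ: {continent: Africa, subregion: central Africa}
  GAB: {continent: Africa, subregion: central Africa}
  COG: {continent: Africa, subregion: central Africa}
  COD: {continent: Africa, subregion: central Africa}
  STP: {continent: Africa, subregion: central Africa}
  # --- Africa: eastern ---
  SDN: {continent: Africa, subregion: eastern Africa}
  SSD: {continent: Africa, subregion: eastern Africa}
  ERI: {continent: Africa, subregion: eastern Africa}
  DJI: {continent: Africa, subregion: eastern Africa}
  ETH: {continent: Africa, subregion: eastern Africa}
  SOM: {continent: Africa, subregion: eastern Africa}
  KEN: {continent: Africa, subregion: eastern Africa}
  UGA: {continent: Africa, subregion: eastern Africa}
  RWA: {continent: Africa, subregion: eastern Africa}
  BDI: {continent: Africa, subregion: eastern Africa}
  TZA: {continent: Africa, subregion: eastern Africa}
  # --- Africa: southern ---
  AGO: {continent: Africa, subregion: southern Africa}
  ZMB: {continent: Africa, subregion: southern Africa}
  MWI: {continent: Africa, subregion: southern Africa}
  MOZ: {continent: Africa, subregion: southern Africa}
  ZWE: {continent: Africa, subregion: southern Africa}
  BWA: {continent: Africa, subregion: southern Africa}
  NAM: {continent: Africa, subregion: southern Africa}
  ZAF: {continent: Africa, subregion: southern Africa}
  LSO: {continent: Africa, subregion: southern Africa}
  SWZ: {continent: Africa, subregion: southern Africa}
  MDG: {continent: Africa, subregion: southern Africa}
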