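# Default chemistry configuration: monoisotopic atomic masses, negative-mode
# adduct definitions, and diacyl lipid class head-group increments (added to
# the diacylglycerol core with condensation water already netted out).
# Override by passing a modified list to the relevant functions or via
# options(oxlipidr.chem = read_chem_config("your.yml")).
isotopes:
  masses:
    C: 12.0
    H: 1.00782503
    "N": 14.00307401   # quoted: a bare N would parse as a YAML boolean
    O: 15.99491462
    P: 30.97376151
  isotope_spacing: 1.0033548
adducts:
  acetate:
    label: "[M+OAc]-"
    delta: C2H3O2
    sign: 1
    charge: -1
  deprotonated:
    label: "[M-H]-"
    delta: H
    sign: -1
    charge: -1
  serine_loss:
    label: "[M-H-C3H5NO2]-"
    delta: C3H6NO2
    sign: -1
    charge: -1
classes:
  PC:   {head_increment: C5H12NO3P, adduct: acetate}
  PE:   {head_increment: C2H6NO3P,  adduct: deprotonated}
  PG:   {head_increment: C3H7O5P,   adduct: deprotonated}
  PI:   {head_increment: C6H11O8P,  adduct: deprotonated}
  PS:   {head_increment: C3H6NO5P,  adduct: serine_loss}
  MGDG: {head_increment: C6H10O5,   adduct: acetate}
  DGDG: {head_increment: C12H20O10, adduct: acetate}
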