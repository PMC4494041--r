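# Valence model: allowed total valences per (element, charge), split into
# common (no finding) and uncommon (Warning "unusual_valence").  A drawn
# valence outside both sets is an Error "bad_valence".  Elements or
# (element, charge) pairs absent from this table are not checked.
#
# The sets are seeded from the MDL V2000 default-valence conventions for the
# organic subset plus the usual hypervalent extensions.  The "uncommon"
# entries are the states a curator should eyeball: pentavalent neutral
# nitrogen as in nitro drawn N(=O)=O, hypervalent halogens, etc.
#
# Charges are string keys ("0", "1", "-1", ...).
"H":
  "0": {common: [1], uncommon: []}
"B":
  "0": {common: [3], uncommon: []}
  "-1": {common: [4], uncommon: []}
"C":
  "0": {common: [4], uncommon: []}
  "1": {common: [3], uncommon: []}
  "-1": {common: [3], uncommon: []}
"N":
  "0": {common: [3], uncommon: [5]}
  "1": {common: [4], uncommon: []}
  "-1": {common: [2], uncommon: []}
"O":
  "0": {common: [2], uncommon: []}
  "1": {common: [3], uncommon: []}
  "-1": {common: [1], uncommon: []}
"F":
  "0": {common: [1], uncommon: []}
  "-1": {common: [0], uncommon: []}
"Si":
  "0": {common: [4], uncommon: [6]}
"P":
  "0": {common: [3, 5], uncommon: []}
  "1": {common: [4], uncommon: []}
  "-1": {common: [2, 4, 6], uncommon: []}
"S":
  "0": {common: [2, 4, 6], uncommon: []}
  "1": {common: [3, 5], uncommon: []}
  "-1": {common: [1], uncommon: []}
"Cl":
  "0": {common: [1], uncommon: [3, 5, 7]}
  "-1": {common: [0], uncommon: []}
"Br":
  "0": {common: [1], uncommon: [3, 5, 7]}
  "-1": {common: [0], uncommon: []}
"I":
  "0": {common: [1], uncommon: [3, 5, 7]}
  "-1": {common: [0], uncommon: []}
"As":
  "0": {common: [3, 5], uncommon: []}
"Sb":
  "0": {common: [3, 5], uncommon: []}
"Se":
  "0": {common: [2, 4, 6], uncommon: []}
"Te":
  "0": {common: [2, 4, 6], uncommon: []}
"Li":
  "0": {common: [1], uncommon: []}
  "1": {common: [0], uncommon: []}
"Na":
  "0": {common: [1], uncommon: []}
  "1": {common: [0], uncommon: []}
"K":
  "0": {common: [1], uncommon: []}
  "1": {common: [0], uncommon: []}
"Mg":
  "0": {common: [2], uncommon: []}
  "2": {common: [0], uncommon: []}
"Ca":
  "0": {common: [2], uncommon: []}
  "2": {common: [0], uncommon: []}
"Al":
  "0": {common: [3], uncommon: []}
  "3": {common: [0], uncommon: []}
"Zn":
  "0": {common: [2], uncommon: []}
  "2": {common: [0], uncommon: []}
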