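# Shared chemistry constants. This file collates before every module that
# uses them at load time.

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1, P = 3, B = 3,
  Si = 4
)

METAL_ELEMENTS <- c(
  "Zn", "Fe", "Cu", "Mn", "Mo", "Mg", "Ca", "Na", "K", "Ni", "Co", "Cd", "Hg"
)

BOND_ORDER_VALUE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

COVALENT_RADIUS <- c(
  C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06, F = 0.71, Cl = 0.99,
  Br = 1.14, I = 1.33, B = 0.82, Si = 1.11, Se = 1.17
)

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")
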