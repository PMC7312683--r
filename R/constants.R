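# Chemical tables used throughout the pipeline: residue naming, reference
# atoms, heavy-atom inventories, hydrogen-bond donor/acceptor sets and the
# hydrophobicity grouping used by the width statistics.

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Hydrophobic / non-hydrophobic split used by the one-sided width tests;
# arginine is excluded from those tests altogether.
HYDROPHOBIC_AA <- c("LEU", "ALA", "ILE", "VAL", "GLY", "PHE", "TRP", "TYR", "MET")
NON_HYDROPHOBIC_AA <- c("ASP", "HIS", "GLU", "GLN", "ASN", "THR", "SER", "LYS",
                        "CYS", "PRO")
EXCLUDED_AA <- "ARG"

DNA_BASES <- c("dA", "dC", "dG", "dT")
PURINES <- c("dA", "dG")
PYRIMIDINES <- c("dC", "dT")

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# One reference atom per groove per base; the minor-groove atom comes first.
REFERENCE_ATOM_MAP <- list(
  dA = c(minor = "N3", major = "N6"),
  dG = c(minor = "N3", major = "O6"),
  dT = c(minor = "O2", major = "O4"),
  dC = c(minor = "O2", major = "N4")
)

# Base heavy atoms (nucleobase only).
BASE_ATOMS <- list(
  dA = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "N6"),
  dG = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "O6", "N2"),
  dT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
  dC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
)

SUGAR_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                           "C3'", "O3'", "C2'", "C1'")
# 5'-terminal nucleotides conventionally lack the phosphate group.
FIVE_PRIME_OPTIONAL_ATOMS <- c("P", "OP1", "OP2")

SUGAR_RING_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

GLYCOSIDIC_N <- c(dA = "N9", dG = "N9", dT = "N1", dC = "N1")

# Atom-name dialect normalization (PDB v2/v3 variants).
ATOM_NAME_ALIASES <- c("O1P" = "OP1", "O2P" = "OP2",
                       "C5*" = "C5'", "C4*" = "C4'", "O4*" = "O4'",
                       "C3*" = "C3'", "O3*" = "O3'", "C2*" = "C2'",
                       "C1*" = "C1'", "O5*" = "O5'",
                       "C5M" = "C7")

RESNAME_ALIASES <- c("DA" = "dA", "DC" = "dC", "DG" = "dG", "DT" = "dT",
                     "dA" = "dA", "dC" = "dC", "dG" = "dG", "dT" = "dT")

# ---------------------------------------------------------------------------
# Hydrogen-bond chemistry.  Each donor carries its heavy-atom antecedent so
# the donor-antecedent--donor--acceptor angle criterion can be evaluated
# without hydrogens.

PROTEIN_DONORS <- list(
  backbone = list(c(donor = "N", antecedent = "CA")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  ASN = list(c("ND2", "CG")),
  GLN = list(c("NE2", "CD")),
  HIS = list(c("ND1", "CG"), c("NE2", "CD2")),
  LYS = list(c("NZ", "CE")),
  SER = list(c("OG", "CB")),
  THR = list(c("OG1", "CB")),
  TRP = list(c("NE1", "CD1")),
  TYR = list(c("OH", "CZ")),
  CYS = list(c("SG", "CB"))
)

PROTEIN_ACCEPTORS <- list(
  backbone = c("O"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = c("OD1"),
  GLN = c("OE1"),
  HIS = c("ND1", "NE2"),
  SER = c("OG"),
  THR = c("OG1"),
  TYR = c("OH")
)

# DNA acceptors by target class.  Phosphate and sugar sets are shared by all
# four bases; base acceptors are per-base.
DNA_PHOSPHATE_ATOMS <- c("OP1", "OP2", "O5'", "O3'")
DNA_SUGAR_ACCEPTORS <- c("O4'")
DNA_BASE_ACCEPTORS <- list(
  dA = c("N1", "N3", "N7"),
  dG = c("N3", "N7", "O6"),
  dT = c("O2", "O4"),
  dC = c("O2", "N3")
)
DNA_BASE_DONORS <- list(
  dA = list(c("N6", "C6")),
  dG = list(c("N1", "C6"), c("N2", "C2")),
  dT = list(c("N3", "C2")),
  dC = list(c("N4", "C4"))
)

# ---------------------------------------------------------------------------
# Sidechain internal coordinates (z-matrix rows: atom, ref3 = parent, ref2,
# ref1, bond length, bond angle, torsion).  Backbone atoms N, CA, C, O and CB
# are constructed separately; rows below hang off them.  Geometry is
# idealized; it is used only to build synthetic probe residues, where the
# heavy-atom inventory and rough shape matter, not crystallographic accuracy.

SIDECHAIN_ZMATRIX <- list(
  ALA = NULL,
  GLY = NULL,
  ARG = list(
    c("CG", "CB", "CA", "N", 1.52, 114, 180),
    c("CD", "CG", "CB", "CA", 1.52, 112, 180),
    c("NE", "CD", "CG", "CB", 1.46, 112, 180),
    c("CZ", "NE", "CD", "CG", 1.33, 124, 180),
    c("NH1", "CZ", "NE", "CD", 1.33, 120, 0),
    c("NH2", "CZ", "NE", "CD", 1.33, 120, 180)),
  ASN = list(
    c("CG", "CB", "CA", "N", 1.52, 113, 180),
    c("OD1", "CG", "CB", "CA", 1.23, 121, -60),
    c("ND2", "CG", "CB", "CA", 1.33, 117, 120)),
  ASP = list(
    c("CG", "CB", "CA", "N", 1.52, 113, 180),
    c("OD1", "CG", "CB", "CA", 1.25, 119, -60),
    c("OD2", "CG", "CB", "CA", 1.25, 119, 120)),
  CYS = list(
    c("SG", "CB", "CA", "N", 1.81, 114, 180)),
  GLN = list(
    c("CG", "CB", "CA", "N", 1.52, 114, 180),
    c("CD", "CG", "CB", "CA", 1.52, 112, 180),
    c("OE1", "CD", "CG", "CB", 1.23, 121, -60),
    c("NE2", "CD", "CG", "CB", 1.33, 117, 120)),
  GLU = list(
    c("CG", "CB", "CA", "N", 1.52, 114, 180),
    c("CD", "CG", "CB", "CA", 1.52, 112, 180),
    c("OE1", "CD", "CG", "CB", 1.25, 119, -60),
    c("OE2", "CD", "CG", "CB", 1.25, 119, 120)),
  HIS = list(
    c("CG", "CB", "CA", "N", 1.50, 114, 180),
    c("ND1", "CG", "CB", "CA", 1.38, 123, -90),
    c("CD2", "CG", "ND1", "CB", 1.36, 109, 180),
    c("CE1", "ND1", "CG", "CB", 1.32, 108, 180),
    c("NE2", "CD2", "CG", "ND1", 1.37, 107, 0)),
  ILE = list(
    c("CG1", "CB", "CA", "N", 1.53, 111, 180),
    c("CG2", "CB", "CA", "CG1", 1.53, 111, -122),
    c("CD1", "CG1", "CB", "CA", 1.52, 114, 180)),
  LEU = list(
    c("CG", "CB", "CA", "N", 1.53, 116, 180),
    c("CD1", "CG", "CB", "CA", 1.52, 111, 60),
    c("CD2", "CG", "CB", "CA", 1.52, 111, -60)),
  LYS = list(
    c("CG", "CB", "CA", "N", 1.52, 114, 180),
    c("CD", "CG", "CB", "CA", 1.52, 112, 180),
    c("CE", "CD", "CG", "CB", 1.52, 112, 180),
    c("NZ", "CE", "CD", "CG", 1.49, 112, 180)),
  MET = list(
    c("CG", "CB", "CA", "N", 1.52, 114, 180),
    c("SD", "CG", "CB", "CA", 1.81, 112, 180),
    c("CE", "SD", "CG", "CB", 1.79, 100, 180)),
  PHE = list(
    c("CG", "CB", "CA", "N", 1.50, 114, 180),
    c("CD1", "CG", "CB", "CA", 1.39, 120, 90),
    c("CD2", "CG", "CD1", "CB", 1.39, 120, 180),
    c("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
    c("CE2", "CD2", "CG", "CD1", 1.39, 120, 0),
    c("CZ", "CE1", "CD1", "CG", 1.39, 120, 0)),
  PRO = list(
    c("CG", "CB", "CA", "N", 1.50, 104, 30),
    c("CD", "CG", "CB", "CA", 1.50, 105, -35)),
  SER = list(
    c("OG", "CB", "CA", "N", 1.42, 111, 180)),
  THR = list(
    c("OG1", "CB", "CA", "N", 1.43, 109, 180),
    c("CG2", "CB", "CA", "OG1", 1.53, 111, -122)),
  TRP = list(
    c("CG", "CB", "CA", "N", 1.50, 114, 180),
    c("CD1", "CG", "CB", "CA", 1.37, 127, 90),
    c("CD2", "CG", "CD1", "CB", 1.43, 126, 180),
    c("NE1", "CD1", "CG", "CD2", 1.38, 110, 0),
    c("CE2", "CD2", "CG", "CD1", 1.41, 107, 0),
    c("CE3", "CD2", "CG", "CD1", 1.40, 133, 180),
    c("CZ2", "CE2", "CD2", "CG", 1.40, 122, 180),
    c("CZ3", "CE3", "CD2", "CE2", 1.39, 118, 180),
    c("CH2", "CZ2", "CE2", "CD2", 1.40, 117, 180)),
  TYR = list(
    c("CG", "CB", "CA", "N", 1.50, 114, 180),
    c("CD1", "CG", "CB", "CA", 1.39, 120, 90),
    c("CD2", "CG", "CD1", "CB", 1.39, 120, 180),
    c("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
    c("CE2", "CD2", "CG", "CD1", 1.39, 120, 0),
    c("CZ", "CE1", "CD1", "CG", 1.39, 120, 0),
    c("OH", "CZ", "CE1", "CD1", 1.38, 120, 180)),
  VAL = list(
    c("CG1", "CB", "CA", "N", 1.53, 111, 180),
    c("CG2", "CB", "CA", "CG1", 1.53, 111, -122))
)
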