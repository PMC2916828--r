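# Bundled representation presets, generated programmatically so the shipped
# files under inst/extdata/presets/ can be regression-tested against the
# generators.

#' The 20 standard amino acids (3-letter codes)
#' @export
AA_STANDARD <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# heavy side-chain atoms per standard residue (PDB naming)
SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# BLOSUM62 substitution matrix over the 20 standard residues (one-letter
# order A R N D C Q E G H I L K M F P S T W Y V), vendored as a constant.
blosum62_matrix <- function() {
  aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  v <- c(
     4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
    -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
    -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
     0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
    -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
     0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
    -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
    -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
     1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
     0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
     0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
  )
  m <- matrix(v, nrow = 20, byrow = TRUE, dimnames = list(aa1, aa1))
  # same residue order, 3-letter codes
  dimnames(m) <- list(
    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  )
  m
}

#' Generate the text of a bundled preset
#'
#' The shipped files under `inst/extdata/presets/` are exactly the output of
#' this generator; see [rep_preset()] for what each preset encodes.
#'
#' @inheritParams rep_preset
#' @return Character vector of definition-file lines.
#' @export
preset_text <- function(name = c("coarse_ca", "ca_centroid_blosum", "chemgroups")) {
  name <- match.arg(name)
  switch(name,
    coarse_ca = preset_coarse_ca(),
    ca_centroid_blosum = preset_ca_centroid_blosum(),
    chemgroups = preset_chemgroups()
  )
}

preset_coarse_ca <- function() {
  c("# Coarse representation: every residue is its C-alpha; any residue",
    "# may be matched with any other.",
    "mode grouped",
    "def * CA",
    "* *")
}

preset_ca_centroid_blosum <- function() {
  out <- c("# C-alpha plus side-chain centroid; matches restricted to residue",
           "# pairs with a BLOSUM62 substitution score of at least -1.",
           "# Glycine has no side chain and is paired on the C-alpha only.",
           "mode grouped")
  for (res in AA_STANDARD) {
    sc <- SIDECHAIN_ATOMS[[res]]
    if (length(sc) == 0L) {
      out <- c(out, sprintf("def %s CA", res))
    } else {
      out <- c(out, sprintf("def %s CA avg(%s):SCC", res, paste(sc, collapse = ",")))
    }
  }
  b62 <- blosum62_matrix()
  for (i in seq_along(AA_STANDARD)) {
    for (j in i:length(AA_STANDARD)) {
      x <- AA_STANDARD[[i]]
      y <- AA_STANDARD[[j]]
      if (b62[x, y] < -1L) next
      gly <- "GLY" %in% c(x, y)
      if (i == j) {
        out <- c(out, x)
      } else if (gly) {
        out <- c(out, sprintf("%s.(CA) %s.(CA)", x, y))
      } else {
        out <- c(out, sprintf("%s %s", x, y))
      }
    }
  }
  out
}

preset_chemgroups <- function() {
  c("# Side-chain chemical-group pseudoatoms, matched as independent points.",
    "# Main-chain atoms are never matched; glycine carries a definition for",
    "# completeness but no rule pairs it.",
    "mode independent",
    "def ALA avg(CB):ALIPH",
    "def VAL avg(CB,CG1,CG2):ALIPH",
    "def LEU avg(CG,CD1,CD2):ALIPH",
    "def ILE avg(CG1,CG2,CD1):ALIPH",
    "def PRO avg(CB,CG,CD):ALIPH",
    "def MET avg(SD):THIO",
    "def CYS avg(SG):THIO",
    "def SER avg(OG):HYDROX",
    "def THR avg(OG1):HYDROX",
    "def TYR avg(OH):HYDROX avg(CG,CD1,CD2,CE1,CE2,CZ):RING",
    "def PHE avg(CG,CD1,CD2,CE1,CE2,CZ):RING",
    "def TRP avg(CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2):RING NE1",
    "def HIS avg(CG,ND1,CD2,CE1,NE2):RING ND1 NE2",
    "def ASP avg(OD1,OD2):CARBOX",
    "def GLU avg(OE1,OE2):CARBOX",
    "def ASN avg(OD1,ND2):AMIDE OD1 ND2",
    "def GLN avg(OE1,NE2):AMIDE OE1 NE2",
    "def LYS NZ",
    "def ARG avg(NE,NH1,NH2,CZ):GUAN",
    "def GLY CA",
    "# equivalences between chemical groups",
    "ALA.(ALIPH) VAL.(ALIPH) LEU.(ALIPH) ILE.(ALIPH) PRO.(ALIPH)",
    "MET.(THIO) CYS.(THIO)",
    "SER.(HYDROX) THR.(HYDROX) TYR.(HYDROX)",
    "TYR.(RING) PHE.(RING) TRP.(RING) HIS.(RING)",
    "ASP.(CARBOX) GLU.(CARBOX)",
    "ASN.(AMIDE) GLN.(AMIDE)",
    paste("HIS.(ND1) HIS.(NE2) ASN.(ND2) GLN.(NE2) TRP.(NE1) LYS.(NZ)",
          "ARG.(GUAN)"),
    paste("ASP.(CARBOX) GLU.(CARBOX) ASN.(OD1) GLN.(OE1) SER.(HYDROX)",
          "THR.(HYDROX) TYR.(HYDROX) HIS.(ND1) HIS.(NE2)"))
}
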