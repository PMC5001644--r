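# Amino acid code tables and the default physicochemical property table.

#' Standard amino acid alphabets
#'
#' `aa_alphabet()` returns the 20 one-letter amino acid codes;
#' `aa_alphabet40()` the 40-symbol conservation-split alphabet in which an
#' uppercase letter denotes a conserved residue of that type and the
#' lowercase letter a non-conserved one.
#'
#' @return Character vector of length 20 or 40.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aa_alphabet
#' @export
aa_alphabet40 <- function() {
  c(aa_alphabet(), tolower(aa_alphabet()))
}

# three-letter -> one-letter lookup (standard residues only)
AA_THREE2ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE2THREE <- structure(names(AA_THREE2ONE), names = unname(AA_THREE2ONE))

#' Default amino acid physicochemical property table
#'
#' Thirteen scalar properties per amino acid, used to build the
#' property-difference block of the stability feature vector. The table is a
#' reconstruction assembled from standard published scales (Kyte-Doolittle
#' hydropathy, residue volume, Grantham polarity, net charge at pH 7,
#' isoelectric point, average flexibility, accessible surface area, residue
#' mass, hydrogen-bond donor/acceptor counts, aromaticity, aliphatic
#' branching, side-chain pKa presence); any 20 x 13 numeric matrix with the
#' amino acids as row names can be supplied in its place.
#'
#' @return A 20 x 13 numeric matrix, rows named by one-letter amino acid
#'   code.
#' @export
aa_property_table <- function() {
  p <- rbind(
    #    hyd   vol  polar chg   pI  flex  asa  mass  don acc  arom brnch pKa
    A = c( 1.8,  88.6, 8.1, 0, 6.00, 0.36, 115, 71.08, 0, 0, 0, 0, 0),
    R = c(-4.5, 173.4,10.5, 1,10.76, 0.53, 225,156.19, 4, 0, 0, 0, 12.5),
    N = c(-3.5, 114.1,11.6, 0, 5.41, 0.46, 160,114.10, 2, 2, 0, 0, 0),
    D = c(-3.5, 111.1,13.0,-1, 2.77, 0.51, 150,115.09, 1, 4, 0, 0, 3.9),
    C = c( 2.5, 108.5, 5.5, 0, 5.07, 0.35, 135,103.14, 1, 0, 0, 0, 8.3),
    Q = c(-3.5, 143.8,10.5, 0, 5.65, 0.49, 180,128.13, 2, 2, 0, 0, 0),
    E = c(-3.5, 138.4,12.3,-1, 3.22, 0.50, 190,129.12, 1, 4, 0, 0, 4.2),
    G = c(-0.4,  60.1, 9.0, 0, 5.97, 0.54, 75,  57.05, 0, 0, 0, 0, 0),
    H = c(-3.2, 153.2,10.4, 0, 7.59, 0.32, 195,137.14, 1, 1, 1, 0, 6.0),
    I = c( 4.5, 166.7, 5.2, 0, 6.02, 0.46, 175,113.16, 0, 0, 0, 1, 0),
    L = c( 3.8, 166.7, 4.9, 0, 5.98, 0.37, 170,113.16, 0, 0, 0, 1, 0),
    K = c(-3.9, 168.6,11.3, 1, 9.74, 0.47, 200,128.17, 2, 0, 0, 0, 10.5),
    M = c( 1.9, 162.9, 5.7, 0, 5.74, 0.30, 185,131.20, 0, 0, 0, 0, 0),
    F = c( 2.8, 189.9, 5.2, 0, 5.48, 0.31, 210,147.18, 0, 0, 1, 0, 0),
    P = c(-1.6, 112.7, 8.0, 0, 6.30, 0.51, 145, 97.12, 0, 0, 0, 0, 0),
    S = c(-0.8,  89.0, 9.2, 0, 5.68, 0.51, 115, 87.08, 1, 1, 0, 0, 0),
    T = c(-0.7, 116.1, 8.6, 0, 5.60, 0.44, 140,101.10, 1, 1, 0, 1, 0),
    W = c(-0.9, 227.8, 5.4, 0, 5.89, 0.31, 255,186.21, 1, 0, 1, 0, 0),
    Y = c(-1.3, 193.6, 6.2, 0, 5.66, 0.42, 230,163.18, 1, 1, 1, 0, 10.1),
    V = c( 4.2, 140.0, 5.9, 0, 5.96, 0.39, 155, 99.13, 0, 0, 0, 1, 0)
  )
  colnames(p) <- c("hydropathy", "volume", "polarity", "charge", "pI",
                   "flexibility", "asa", "mass", "hbond_donor",
                   "hbond_acceptor", "aromatic", "branched", "side_pKa")
  p
}

# default metal heteroatom codes recognised by label_metal_sites()
METAL_CODES <- c(ZN = "Zn", CA = "Ca", MG = "Mg", FE = "Fe", CU = "Cu",
                 MN = "Mn", NI = "Ni", CO = "Co", "NA" = "Na", K = "K",
                 CD = "Cd")
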