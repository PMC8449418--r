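# Physical constants and per-residue chemistry tables used throughout.
# Scattering lengths are bound coherent values in fm (1 fm = 1e-13 cm);
# atomic volumes are the displaced-solvent values of Fraser, MacRae &
# Suzuki (1978), the set conventionally used for excluded-volume terms.

#' Avogadro's constant (exact SI value), mol^-1
#' @keywords internal
.NA_AVOGADRO <- 6.02214076e23

# coherent neutron scattering lengths, fm
.NEUTRON_B_FM <- c(
  H = -3.7390,
  D = 6.6710,
  C = 6.6460,
  N = 9.3600,
  O = 5.8030,
  S = 2.8470,
  P = 5.1300,
  SE = 7.9700
)

# displaced atomic volumes, Angstrom^3
.ATOM_VOLUME_A3 <- c(
  H = 5.15,
  D = 5.15,
  C = 16.44,
  N = 2.49,
  O = 9.13,
  S = 19.86,
  P = 5.73,
  SE = 28.73
)

#' Scattering length density of the solvent, cm^-2
#'
#' Computed from the molecular scattering lengths and molecular volumes of
#' H2O (29.9 A^3) and D2O (30.1 A^3), linearly mixed by volume fraction.
#' Pure D2O evaluates to ~6.36e10 cm^-2, pure H2O to ~-0.56e10 cm^-2.
#'
#' @param d2o_fraction volume fraction of D2O in the solvent, in \[0, 1\].
#' @return scattering length density in cm^-2.
#' @export
solvent_sld <- function(d2o_fraction) {
  stopifnot(is.numeric(d2o_fraction), d2o_fraction >= 0, d2o_fraction <= 1)
  b_h2o <- (2 * .NEUTRON_B_FM[["H"]] + .NEUTRON_B_FM[["O"]]) * 1e-13 # cm
  b_d2o <- (2 * .NEUTRON_B_FM[["D"]] + .NEUTRON_B_FM[["O"]]) * 1e-13
  v_h2o <- 29.9e-24 # cm^3
  v_d2o <- 30.1e-24
  rho_h2o <- b_h2o / v_h2o
  rho_d2o <- b_d2o / v_d2o
  (1 - d2o_fraction) * rho_h2o + d2o_fraction * rho_d2o
}

# Per-residue hydrogen templates at standard (neutral-pH) protonation:
# for each heavy atom, the number of attached hydrogens and how many of
# them are labile (bonded to N/O/S, hence exchangeable in D2O).
# Backbone N carries the amide hydrogen (none for proline); Asp/Glu are
# deprotonated, Lys/Arg protonated, His singly protonated on NE2.
.residue_h_template <- function() {
  bb <- function(gly = FALSE) {
    if (gly) {
      list(N = c(1L, 1L), CA = c(2L, 0L), C = c(0L, 0L), O = c(0L, 0L))
    } else {
      list(N = c(1L, 1L), CA = c(1L, 0L), C = c(0L, 0L), O = c(0L, 0L))
    }
  }
  sc <- list(
    ALA = list(CB = c(3L, 0L)),
    ARG = list(CB = c(2L, 0L), CG = c(2L, 0L), CD = c(2L, 0L),
               NE = c(1L, 1L), CZ = c(0L, 0L),
               NH1 = c(2L, 2L), NH2 = c(2L, 2L)),
    ASN = list(CB = c(2L, 0L), CG = c(0L, 0L), OD1 = c(0L, 0L),
               ND2 = c(2L, 2L)),
    ASP = list(CB = c(2L, 0L), CG = c(0L, 0L), OD1 = c(0L, 0L),
               OD2 = c(0L, 0L)),
    CYS = list(CB = c(2L, 0L), SG = c(1L, 1L)),
    GLN = list(CB = c(2L, 0L), CG = c(2L, 0L), CD = c(0L, 0L),
               OE1 = c(0L, 0L), NE2 = c(2L, 2L)),
    GLU = list(CB = c(2L, 0L), CG = c(2L, 0L), CD = c(0L, 0L),
               OE1 = c(0L, 0L), OE2 = c(0L, 0L)),
    GLY = list(),
    HIS = list(CB = c(2L, 0L), CG = c(0L, 0L), ND1 = c(0L, 0L),
               CD2 = c(1L, 0L), CE1 = c(1L, 0L), NE2 = c(1L, 1L)),
    ILE = list(CB = c(1L, 0L), CG1 = c(2L, 0L), CG2 = c(3L, 0L),
               CD1 = c(3L, 0L)),
    LEU = list(CB = c(2L, 0L), CG = c(1L, 0L), CD1 = c(3L, 0L),
               CD2 = c(3L, 0L)),
    LYS = list(CB = c(2L, 0L), CG = c(2L, 0L), CD = c(2L, 0L),
               CE = c(2L, 0L), NZ = c(3L, 3L)),
    MET = list(CB = c(2L, 0L), CG = c(2L, 0L), SD = c(0L, 0L),
               CE = c(3L, 0L)),
    PHE = list(CB = c(2L, 0L), CG = c(0L, 0L), CD1 = c(1L, 0L),
               CD2 = c(1L, 0L), CE1 = c(1L, 0L), CE2 = c(1L, 0L),
               CZ = c(1L, 0L)),
    PRO = list(CB = c(2L, 0L), CG = c(2L, 0L), CD = c(2L, 0L)),
    SER = list(CB = c(2L, 0L), OG = c(1L, 1L)),
    THR = list(CB = c(1L, 0L), OG1 = c(1L, 1L), CG2 = c(3L, 0L)),
    TRP = list(CB = c(2L, 0L), CG = c(0L, 0L), CD1 = c(1L, 0L),
               CD2 = c(0L, 0L), NE1 = c(1L, 1L), CE2 = c(0L, 0L),
               CE3 = c(1L, 0L), CZ2 = c(1L, 0L), CZ3 = c(1L, 0L),
               CH2 = c(1L, 0L)),
    TYR = list(CB = c(2L, 0L), CG = c(0L, 0L), CD1 = c(1L, 0L),
               CD2 = c(1L, 0L), CE1 = c(1L, 0L), CE2 = c(1L, 0L),
               CZ = c(0L, 0L), OH = c(1L, 1L)),
    VAL = list(CB = c(1L, 0L), CG1 = c(3L, 0L), CG2 = c(3L, 0L))
  )
  out <- lapply(names(sc), function(rn) {
    c(bb(gly = identical(rn, "GLY")), sc[[rn]])
  })
  names(out) <- names(sc)
  # proline has no amide hydrogen
  out$PRO$N <- c(0L, 0L)
  out
}

.RESIDUE_H <- .residue_h_template()

# Average residue (i.e. amino acid minus water) masses, g/mol.
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.WATER_MASS <- 18.0153

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Residues whose side chain gains one labile hydrogen when protonated
# (carboxylates); histidine gains one on ND1 when doubly protonated.
.PROTONATABLE_ATOM <- c(ASP = "OD2", GLU = "OE2", HIS = "ND1")

#' Neutron scattering length of an element
#'
#' @param element character vector of element symbols (e.g. "C", "N").
#' @return bound coherent scattering length(s) in cm.
#' @export
neutron_b <- function(element) {
  b <- .NEUTRON_B_FM[toupper(element)]
  if (anyNA(b)) {
    stop("no neutron scattering length tabulated for element(s): ",
         paste(unique(element[is.na(b)]), collapse = ", "))
  }
  unname(b) * 1e-13
}

#' Displaced atomic volume of an element
#'
#' @param element character vector of element symbols.
#' @return displaced solvent volume(s) in Angstrom^3.
#' @export
atom_volume <- function(element) {
  v <- .ATOM_VOLUME_A3[toupper(element)]
  if (anyNA(v)) {
    stop("no atomic volume tabulated for element(s): ",
         paste(unique(element[is.na(v)]), collapse = ", "))
  }
  unname(v)
}
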