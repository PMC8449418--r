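# Shared fixtures and independent oracle tables. Everything is built
# in code at test time; toys are constructed once per test run.

# unit-contrast solvent: beads scatter with their bare b, no excluded
# volume term, which makes closed-form oracles exact
unit_solvent <- function() solvent_spec(rho_solvent = 0)

toy_closed <- make_toy_pentamer(toy_spec(u = 0))
toy_open <- make_toy_pentamer(toy_spec(u = 1))

# Independent residue-formula oracle: hydrogen counts of each residue
# (= amino acid minus water) in the protonation state prevailing at
# neutral pH (Arg/Lys protonated, Asp/Glu deprotonated, His neutral).
# Derived from molecular formulas, not from the package's templates.
FORMULA_H <- c(
  ALA = 5, ARG = 13, ASN = 6, ASP = 4, CYS = 5, GLN = 8, GLU = 6,
  GLY = 3, HIS = 7, ILE = 11, LEU = 11, LYS = 13, MET = 9, PHE = 9,
  PRO = 7, SER = 5, THR = 7, TRP = 10, TYR = 9, VAL = 9
)

# Build an atomic model for an arbitrary residue sequence directly
# from heavy-atom topology (coordinates are an arbitrary spiral: mass,
# volume and hydrogen bookkeeping do not depend on geometry).
fake_protein <- function(res3, chain = "A") {
  heavy <- list(
    ALA = c("N","CA","C","O","CB"),
    ARG = c("N","CA","C","O","CB","CG","CD","NE","CZ","NH1","NH2"),
    ASN = c("N","CA","C","O","CB","CG","OD1","ND2"),
    ASP = c("N","CA","C","O","CB","CG","OD1","OD2"),
    CYS = c("N","CA","C","O","CB","SG"),
    GLN = c("N","CA","C","O","CB","CG","CD","OE1","NE2"),
    GLU = c("N","CA","C","O","CB","CG","CD","OE1","OE2"),
    GLY = c("N","CA","C","O"),
    HIS = c("N","CA","C","O","CB","CG","ND1","CD2","CE1","NE2"),
    ILE = c("N","CA","C","O","CB","CG1","CG2","CD1"),
    LEU = c("N","CA","C","O","CB","CG","CD1","CD2"),
    LYS = c("N","CA","C","O","CB","CG","CD","CE","NZ"),
    MET = c("N","CA","C","O","CB","CG","SD","CE"),
    PHE = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ"),
    PRO = c("N","CA","C","O","CB","CG","CD"),
    SER = c("N","CA","C","O","CB","OG"),
    THR = c("N","CA","C","O","CB","OG1","CG2"),
    TRP = c("N","CA","C","O","CB","CG","CD1","CD2","NE1","CE2",
            "CE3","CZ2","CZ3","CH2"),
    TYR = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2",
            "CZ","OH"),
    VAL = c("N","CA","C","O","CB","CG1","CG2")
  )
  rows <- list()
  k <- 0
  for (i in seq_along(res3)) {
    for (at in heavy[[res3[i]]]) {
      k <- k + 1
      el <- substr(at, 1, 1)
      rows[[k]] <- data.frame(
        element = el,
        # compact globular arrangement (a jittered grid): chemistry
        # tests ignore geometry, scattering tests want a sane Rg
        x = 3.5 * (k %% 7) + 0.3 * sin(k),
        y = 3.5 * ((k %/% 7) %% 7) + 0.3 * cos(2 * k),
        z = 3.5 * (k %/% 49) + 0.3 * sin(3 * k),
        resname = res3[i], resno = i, chain = chain, atom_name = at,
        occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  atomic_model(do.call(rbind, rows))
}

# minimal handwritten PDB: glycine backbone in chain A plus one
# alanine in chain B, with an altloc pair on the B CA
pdb_fixture_text <- c(
  "HEADER    TEST FIXTURE",
  "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
  "ATOM      4  N   ALA B   1       2.000   1.000   0.000  1.00  0.00           N",
  "ATOM      5  CA AALA B   1       3.400   1.000   0.000  0.70  0.00           C",
  "ATOM      6  CA BALA B   1       3.900   1.500   0.000  0.30  0.00           C",
  "ATOM      7  C   ALA B   1       4.100   2.300   0.000  1.00  0.00           C",
  "ATOM      8  O   ALA B   1       5.300   2.300   0.000  1.00  0.00           O",
  "ATOM      9  CB  ALA B   1       3.900   0.000   1.000  1.00  0.00           C",
  "TER",
  "END"
)

write_pdb_fixture <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(pdb_fixture_text, path)
  path
}

# fm -> cm
FM <- 1e-13
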