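# Force-field and physical-constant tables.
#
# The docking engine uses a deliberately compact, element-keyed Lennard-Jones
# parameterization plus Gasteiger-Marsili partial charges for ligands and a
# small per-residue charge template for receptors. All tables are data-driven
# so a richer force field (e.g. full MMFF94 typing) can be dropped in without
# touching the energy code.

# Coulomb constant in kcal*A/(mol*e^2)
.kcoulomb <- 332.06
# Born self-energy constant: 0.5 * 332.06
.kborn <- 166.03

# Per-element Lennard-Jones parameters. `rmin` is the homonuclear pair
# minimum-energy distance (A); pairs combine by Lorentz-Berthelot rules
# (arithmetic rmin, geometric epsilon). `eps` in kcal/mol.
.lj_table <- function() {
  tibble::tribble(
    ~element, ~eps,  ~rmin,
    "H",      0.016, 2.40,
    "C",      0.086, 3.80,
    "N",      0.170, 3.50,
    "O",      0.210, 3.30,
    "F",      0.061, 3.20,
    "P",      0.200, 4.10,
    "S",      0.250, 4.00,
    "Cl",     0.265, 3.90,
    "Br",     0.320, 4.20,
    "I",      0.400, 4.50,
    "Du",     0.000, 1.00
  )
}

.lj_lookup <- function(elements) {
  tab <- .lj_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    miss <- unique(elements[is.na(idx)])
    # unparameterized elements fall back to carbon-like values
    warn(paste0("No Lennard-Jones parameters for element(s) ",
                paste(miss, collapse = ", "), "; using carbon values."))
    idx[is.na(idx)] <- match("C", tab$element)
  }
  list(eps = tab$eps[idx], rmin = tab$rmin[idx])
}

# Most-abundant-isotope masses (Da), used for monoisotopic mass computation.
.isotope_masses <- c(
  H = 1.00782503207, He = 4.00260325, B = 11.00930536, C = 12.0,
  N = 14.0030740048, O = 15.9949146196, F = 18.99840322, Na = 22.98976928,
  Mg = 23.98504170, Si = 27.97692653, P = 30.97376163, S = 31.97207100,
  Cl = 34.96885268, K = 38.96370668, Ca = 39.96259098, Fe = 55.93493743,
  Zn = 63.92914201, Se = 79.91652137, Br = 78.9183371, I = 126.904473
)
.proton_mass <- 1.007276466

# Gasteiger-Marsili electronegativity coefficients chi(q) = a + b q + c q^2,
# keyed by element and hybridization ("sp3", "sp2", "sp").
.gasteiger_params <- function() {
  tibble::tribble(
    ~key,    ~a,    ~b,    ~c,
    "H",     7.17,  6.24, -0.56,
    "C.sp3", 7.98,  9.18,  1.88,
    "C.sp2", 8.79,  9.32,  1.51,
    "C.sp",  10.39, 9.45,  0.73,
    "N.sp3", 11.54, 10.82, 1.36,
    "N.sp2", 12.87, 11.15, 0.85,
    "N.sp",  15.68, 11.70, -0.27,
    "O.sp3", 14.18, 12.92, 1.39,
    "O.sp2", 17.07, 13.79, 0.47,
    "F",     14.66, 13.85, 2.31,
    "Cl",    11.00, 9.69,  1.35,
    "Br",    10.08, 8.47,  1.16,
    "I",     9.90,  7.96,  0.96,
    "S.sp3", 10.14, 9.13,  1.38,
    "S.sp2", 10.14, 9.13,  1.38,
    "P.sp3", 8.90,  8.24,  0.96
  )
}

# Receptor partial-charge template: residue-specific atom charges (elementary
# units) at pH 7.4 protonation states. Atoms not listed are neutral. A reduced
# backbone dipole is included so that grid electrostatics see peptide polarity.
.residue_charges <- function() {
  list(
    backbone = c(N = -0.35, H = 0.35, C = 0.45, O = -0.45),
    ASP = c(OD1 = -0.5, OD2 = -0.5),
    GLU = c(OE1 = -0.5, OE2 = -0.5),
    LYS = c(NZ = 0.4, HZ1 = 0.2, HZ2 = 0.2, HZ3 = 0.2),
    ARG = c(NH1 = 0.2, NH2 = 0.2, NE = 0.1, HE = 0.1,
            HH11 = 0.1, HH12 = 0.1, HH21 = 0.1, HH22 = 0.1),
    HIS = c(ND1 = -0.2, NE2 = -0.2, HE2 = 0.4),
    SER = c(OG = -0.4, HG = 0.4),
    THR = c(OG1 = -0.4, HG1 = 0.4),
    TYR = c(OH = -0.4, HH = 0.4),
    CYS = c(SG = -0.2, HG = 0.2),
    ASN = c(OD1 = -0.4, ND2 = -0.3, HD21 = 0.35, HD22 = 0.35),
    GLN = c(OE1 = -0.4, NE2 = -0.3, HE21 = 0.35, HE22 = 0.35),
    TRP = c(NE1 = -0.3, HE1 = 0.3)
  )
}

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.water_residues <- c("HOH", "WAT", "H2O", "TIP", "TIP3")

# Polar-hydrogen rule table: donor heavy atom name -> number of hydrogens to
# add at pH 7.4 (His modelled as the neutral NE2-H tautomer).
.polar_h_rules <- function() {
  list(
    backbone_N = 1, # except proline
    SER = c(OG = 1), THR = c(OG1 = 1), TYR = c(OH = 1),
    LYS = c(NZ = 3), ARG = c(NE = 1, NH1 = 2, NH2 = 2),
    ASN = c(ND2 = 2), GLN = c(NE2 = 2), HIS = c(NE2 = 1),
    TRP = c(NE1 = 1), CYS = c(SG = 1)
  )
}
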