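# Idealized base geometries in the standard nucleic-acid reference frame
# (Tsukuba convention: origin between the paired bases, x toward the major
# groove, y along the pairing edge toward the reference-strand sugar, z the
# base normal, right-handed).  In this frame an ideal Watson-Crick partner is
# obtained by negating y and z.  Coordinates in Angstrom; base atoms are
# exact, the attached sugar-phosphate template is idealized and decorative
# (analysis frames fit ring atoms only).

.std_base_atoms <- local({
  A <- rbind(
    N9 = c(-1.291, 4.498, 0.000),
    C8 = c( 0.024, 4.897, 0.000),
    N7 = c( 0.877, 3.902, 0.000),
    C5 = c( 0.071, 2.771, 0.000),
    C6 = c( 0.369, 1.398, 0.000),
    N6 = c( 1.611, 0.909, 0.000),
    N1 = c(-0.668, 0.532, 0.000),
    C2 = c(-1.912, 1.023, 0.000),
    N3 = c(-2.320, 2.290, 0.000),
    C4 = c(-1.267, 3.124, 0.000))
  G <- rbind(
    N9 = c(-1.289, 4.551, 0.000),
    C8 = c( 0.023, 4.962, 0.000),
    N7 = c( 0.870, 3.969, 0.000),
    C5 = c( 0.071, 2.833, 0.000),
    C6 = c( 0.424, 1.460, 0.000),
    O6 = c( 1.554, 0.955, 0.000),
    N1 = c(-0.700, 0.641, 0.000),
    C2 = c(-1.999, 1.087, 0.000),
    N2 = c(-2.949, 0.139, -0.001),
    N3 = c(-2.342, 2.364, 0.001),
    C4 = c(-1.265, 3.177, 0.000))
  C <- rbind(
    N1 = c(-1.285, 4.542, 0.000),
    C2 = c(-1.472, 3.158, 0.000),
    O2 = c(-2.628, 2.709, 0.001),
    N3 = c(-0.391, 2.344, 0.000),
    C4 = c( 0.837, 2.868, 0.000),
    N4 = c( 1.875, 2.027, 0.001),
    C5 = c( 1.056, 4.275, 0.000),
    C6 = c(-0.023, 5.068, 0.000))
  T <- rbind(
    N1 = c(-1.284, 4.500, 0.000),
    C2 = c(-1.462, 3.135, 0.000),
    O2 = c(-2.562, 2.608, 0.000),
    N3 = c(-0.298, 2.407, 0.000),
    C4 = c( 0.994, 2.897, 0.000),
    O4 = c( 1.944, 2.119, 0.000),
    C5 = c( 1.106, 4.338, 0.000),
    C7 = c( 2.466, 4.961, 0.001),
    C6 = c(-0.024, 5.057, 0.000))
  lapply(list(A = A, C = C, G = G, T = T), function(m) {
    colnames(m) <- c("x", "y", "z")
    m
  })
})

# Idealized, rigid sugar-phosphate template shared by all four bases,
# positioned off the glycosidic nitrogen.  Decorative by design: bond
# geometry is plausible but the backbone is not re-puckered at kinked or
# unwound steps.
.std_backbone_atoms <- local({
  m <- rbind(
    "C1'" = c(-2.477, 5.400, 0.000),
    "O4'" = c(-3.484, 5.187, 0.986),
    "C2'" = c(-2.963, 6.316, -1.110),
    "C3'" = c(-4.433, 6.659, -0.850),
    "O3'" = c(-4.598, 8.059, -0.667),
    "C4'" = c(-4.775, 5.815, 0.374),
    "C5'" = c(-6.165, 5.929, 0.964),
    "O5'" = c(-6.233, 5.125, 2.140),
    "P"   = c(-7.575, 5.200, 2.990),
    "OP1" = c(-8.700, 4.800, 2.120),
    "OP2" = c(-7.500, 4.350, 4.210))
  colnames(m) <- c("x", "y", "z")
  m
})

# Purine vs pyrimidine ring atoms used for frame fitting.
.ring_atoms <- list(
  purine     = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6"))

.base_class <- c(A = "purine", G = "purine", C = "pyrimidine", T = "pyrimidine")

.wc_complement <- c(A = "T", T = "A", G = "C", C = "G")

# Canonical Watson-Crick donor/acceptor atom pairs, named (reference base
# atom, partner base atom), keyed by the reference base.
.wc_hbonds <- list(
  A = list(c("N1", "N3"), c("N6", "O4")),
  T = list(c("N3", "N1"), c("O4", "N6")),
  G = list(c("N1", "N3"), c("O6", "N4"), c("N2", "O2")),
  C = list(c("N3", "N1"), c("N4", "O6"), c("O2", "N2")))

#' Standard base geometry
#'
#' Atom coordinates of an idealized base (optionally with the idealized
#' sugar-phosphate template) in the standard reference frame.
#'
#' @param base one of "A", "C", "G", "T".
#' @param backbone include the decorative sugar-phosphate template atoms.
#' @return numeric matrix with rownames = atom names, columns x, y, z (A).
#' @export
standard_base <- function(base, backbone = FALSE) {
  base <- toupper(base)
  if (!base %in% names(.std_base_atoms))
    stop("unknown base '", base, "' (expected A, C, G or T)")
  m <- .std_base_atoms[[base]]
  if (backbone) m <- rbind(m, .std_backbone_atoms)
  m
}

# Ring-atom subset of the standard base, in canonical order.
standard_ring <- function(base) {
  base <- toupper(base)
  standard_base(base)[.ring_atoms[[.base_class[[base]]]], , drop = FALSE]
}

# One-letter base code from a residue name (DA, DT, ... or A, U, ...).
base_code <- function(resid) {
  r <- toupper(trimws(resid))
  map <- c(DA = "A", DC = "C", DG = "G", DT = "T", DI = "I",
           A = "A", C = "C", G = "G", U = "U", I = "I", T = "T")
  unname(map[r])
}
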