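# Shared fixtures, built in code at test time.

# A deterministic random proper rotation (QR of a seeded normal matrix).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_translation <- function(seed, scale = 50) {
  set.seed(seed + 1000)
  rnorm(3, sd = scale)
}

# Ideal 19-bp spacer duplex (36 deg/step, 3.38 A rise), alternating sequence.
ideal_spacer_19 <- function() {
  sq <- paste(rep(c("A", "T", "G", "C"), 5)[1:19], collapse = "")
  build_duplex(step_schedule(sq))
}

# Regulator-remodeled spacer emulation: 19 bp unwound by 82 deg total, a
# central kink calibrated to read 58 deg under the 6/7/6 centroid method,
# and the central pair opened.
remodeled_spacer <- function(kink = 58, unwind = 82) {
  sq <- paste(rep(c("A", "T", "G", "C"), 5)[1:19], collapse = "")
  sch <- impose_unwinding(step_schedule(sq), unwind)
  sch <- impose_centroid_kink(sch, 10, kink)
  open_bubble(build_duplex(sch), 10)
}

# Minimal hand-written one-atom PDB file; returns the path.
one_atom_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END"), path)
  path
}

# Small hand-written mmCIF: a 2-bp DNA duplex (chains X, Y) plus two glycine
# CA records (chain P).  Counts are known from the text below.
tiny_mmcif <- function(path = tempfile(fileext = ".cif")) {
  hdr <- c(
    "data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  d <- build_duplex(step_schedule("AT"), backbone = FALSE)
  at <- d$model$atoms
  at$chain <- ifelse(at$chain == "A", "X", "Y")
  rows <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 20.00 %d %s %s %s 1",
            i, at$element[i], at$elety[i], at$resid[i], at$chain[i],
            at$resno[i], at$x[i], at$y[i], at$z[i], at$resno[i], at$resid[i],
            at$chain[i], at$elety[i])
  }, character(1))
  np <- nrow(at)
  prot <- c(
    sprintf("ATOM %d C CA . GLY P 2 1 ? 0.000 0.000 -10.000 1.00 15.00 1 GLY P CA 1", np + 1),
    sprintf("ATOM %d C CA . GLY P 2 2 ? 3.800 0.000 -10.000 1.00 15.00 2 GLY P CA 1", np + 2))
  writeLines(c(hdr, rows, prot), path)
  list(path = path, n_dna_atoms = np, n_dna_res = 4, n_prot_res = 2)
}

# Synthetic protein-like CA trace: n_res pseudo-residues along an
# alpha-helical curve (radius 2.3 A, 100 deg/res, 1.5 A rise).
helix_ca <- function(n_res, chain = "A", offset = c(0, 0, 0), resno0 = 1) {
  i <- seq_len(n_res) - 1
  th <- i * 100 * pi / 180
  data.frame(chain = chain, resno = resno0 + i, insert = "", resid = "ALA",
             elety = "CA", element = "C", alt = "",
             x = 2.3 * cos(th) + offset[1],
             y = 2.3 * sin(th) + offset[2],
             z = 1.5 * i + offset[3],
             occ = 1, b = 0, stringsAsFactors = FALSE)
}

# Two-state fixture for domain motion: reference chain R stays put, domain
# chain D rotates `angle` deg about a hinge axis and its centroid moves
# `dist` A.
two_state_models <- function(angle = 39, dist = 21, seed = 7) {
  ref <- helix_ca(30, chain = "R")
  dom <- helix_ca(25, chain = "D", offset = c(15, 0, 0))
  state1 <- structure_model(rbind(ref, dom), entry_id = "state1")
  R <- rotation_about(c(0, 1, 1), angle)
  xyz <- as.matrix(dom[, c("x", "y", "z")])
  cen <- colMeans(xyz)
  rotated <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen, "+")
  set.seed(seed)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rotated <- sweep(rotated, 2, dir * dist, "+")
  dom2 <- dom
  dom2[, c("x", "y", "z")] <- rotated
  state2 <- structure_model(rbind(ref, dom2), entry_id = "state2")
  list(state1 = state1, state2 = state2)
}

# Exact exposed area of two overlapping spheres (analytic spherical caps):
# per-sphere accessible areas for expanded radii r1, r2 at center distance d.
two_sphere_exact <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1,
    4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Rotation angle of a 3x3 rotation matrix via eigen-decomposition (an
# independent oracle for h-twist / axis-angle code paths).
eigen_rotation_angle <- function(R) {
  ev <- eigen(R)$values
  k <- which.max(abs(Im(ev)))
  abs(atan2(Im(ev[k]), Re(ev[k]))) * 180 / pi
}
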