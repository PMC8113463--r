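# Rigid-body superposition (Kabsch), domain-motion quantification between
# conformational states, and Shrake-Rupley solvent-accessible / buried
# surface areas.

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto `target`
#' (reflections excluded by sign correction), with the residual RMSD.
#' The fit satisfies target ~ mobile %*% t(rotation) + translation.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3,
#'   non-collinear).
#' @return a `superposition_result`: rotation (3x3, det +1), translation
#'   (3-vector), rmsd (A), n_atoms.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mobile and target must have the same dimensions")
  if (ncol(mobile) != 3) stop("coordinate matrices must be n x 3")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  sv <- tryCatch(svd(t(X) %*% Y), error = function(e) stop("degenerate input: ", conditionMessage(e)))
  if (sv$d[2] < 1e-10)
    stop("collinear or degenerate input: points do not span a plane")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  aa <- axis_angle(x$rotation)
  cat(sprintf("<superposition> %d atoms, rmsd %.3f A, rotation %.2f deg\n",
              x$n_atoms, x$rmsd, aa$angle))
  invisible(x)
}

# Apply a superposition to an n x 3 coordinate matrix.
apply_superposition <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}

# Matched coordinate sets for a selection in two states: residues matched by
# (chain, resno, insert); unmatched residues dropped with a warning.
matched_coords <- function(state1, state2, selection, atom_names = "CA") {
  s1 <- select_atoms(state1, selection)
  s2 <- select_atoms(state2, selection)
  a1 <- s1$atoms[s1$atoms$elety %in% atom_names & !s1$atoms$hydrogen, ]
  a2 <- s2$atoms[s2$atoms$elety %in% atom_names & !s2$atoms$hydrogen, ]
  k1 <- paste(residue_key(a1), a1$elety)
  k2 <- paste(residue_key(a2), a2$elety)
  common <- intersect(k1, k2)
  dropped <- length(union(k1, k2)) - length(common)
  if (dropped > 0)
    warning(dropped, " unmatched atom(s) dropped for selection '", selection, "'")
  list(xyz1 = as.matrix(a1[match(common, k1), c("x", "y", "z")]),
       xyz2 = as.matrix(a2[match(common, k2), c("x", "y", "z")]))
}

#' Rigid-body motion of a domain between two states
#'
#' State 2 is superposed onto state 1 using the C-alpha atoms of
#' `reference_sel` (the fixed frame, e.g. the polymerase core); the domain
#' motion is then the Kabsch rotation between the `domain_sel` C-alpha sets
#' of state 1 and the aligned state 2, with the centroid displacement
#' measured after reference alignment.
#'
#' @param state1,state2 [structure_model] objects for the two states.
#' @param reference_sel selection expression for the reference frame.
#' @param domain_sel selection expression for the moving domain.
#' @param atom_names atoms used for matching (default backbone C-alpha).
#' @return a `domain_motion`: rotation_angle (deg), centroid_displacement
#'   (A), axis (unit 3-vector), reference_rmsd, n_atoms.
#' @export
domain_motion <- function(state1, state2, reference_sel, domain_sel,
                          atom_names = "CA") {
  ref <- matched_coords(state1, state2, reference_sel, atom_names)
  if (nrow(ref$xyz1) < 3) stop("empty or too-small reference selection")
  sp_ref <- kabsch_superpose(ref$xyz2, ref$xyz1)
  dom <- matched_coords(state1, state2, domain_sel, atom_names)
  if (nrow(dom$xyz1) < 3) stop("fewer than 3 matched domain atoms")
  dom2_aligned <- apply_superposition(dom$xyz2, sp_ref)
  sp_dom <- kabsch_superpose(dom$xyz1, dom2_aligned)
  aa <- axis_angle(sp_dom$rotation)
  disp <- vnorm(colMeans(dom2_aligned) - colMeans(dom$xyz1))
  structure(list(rotation_angle = aa$angle, centroid_displacement = disp,
                 axis = aa$axis, reference_rmsd = sp_ref$rmsd,
                 domain_rmsd = sp_dom$rmsd, n_atoms = nrow(dom$xyz1)),
            class = "domain_motion")
}

#' @export
print.domain_motion <- function(x, ...) {
  cat(sprintf(paste0("<domain_motion> rotation %.1f deg, centroid moves ",
                     "%.1f A (%d atoms; reference rmsd %.2f A)\n"),
              x$rotation_angle, x$centroid_displacement, x$n_atoms,
              x$reference_rmsd))
  invisible(x)
}

# Bondi-type van der Waals radii (A).
.vdw_radii <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90, MG = 1.73, ZN = 1.39, FE = 1.80, MN = 1.73,
                "NA" = 2.27, K = 2.75, CA = 2.31)

vdw_radius <- function(element, default_radius = 1.70) {
  el <- toupper(trimws(element))
  r <- .vdw_radii[el]
  if (any(is.na(r))) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over the van der Waals surface using a
#' deterministic golden-spiral point set: each atom's accessible fraction is
#' the share of its expanded-sphere points not buried inside any neighbor's
#' expanded sphere, times 4*pi*(r + probe)^2.  Hydrogens are excluded by
#' default.
#'
#' @param model a [structure_model] (or atom table).
#' @param probe probe radius in A (default 1.4, water).
#' @param n_points sphere points per atom (default 960).
#' @param include_hydrogens include hydrogens in the calculation.
#' @param default_radius radius for elements missing from the embedded
#'   Bondi-type set.
#' @return a `sasa_result`: per-atom areas (A^2, aligned with the atom table
#'   used), per-residue sums, total, and the parameters used.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960,
                 include_hydrogens = FALSE, default_radius = 1.70) {
  at <- if (inherits(model, "structure_model")) model$atoms else model
  if (!include_hydrogens) at <- at[!at$hydrogen, , drop = FALSE]
  n <- nrow(at)
  if (n == 0) stop("no atoms for SASA")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- vdw_radius(at$element, default_radius) + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbor search on a grid would be overkill at these sizes; use cutoff
  # by pairwise distance per atom
  max_r <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + max_r & seq_len(n) != i)
    nb <- nb[di[nb] < rad[i] + rad[nb]]
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- colSums((t(surf) - xyz[j, ])^2)
        acc <- acc & d2 > rad[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * rad[i]^2
  }
  key <- residue_key(at)
  per_res <- tapply(area, key, sum)
  structure(list(per_atom = area, atoms = at,
                 per_residue = per_res, total = sum(area),
                 probe = probe, n_points = n_points,
                 radii_set = "bondi"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Buried surface area between two selections
#'
#' Two-sided delta-SASA: SASA(A alone) + SASA(B alone) - SASA(A and B
#' together), with all other chains excluded from the calculation.  The
#' conventional one-sided interface area (half the total) is reported
#' alongside.
#'
#' @param complex a [structure_model] containing both components.
#' @param sel_a,sel_b disjoint selection expressions for the two sides.
#' @param ... passed to [sasa()] (probe, n_points, ...).
#' @return a `bsa_result`: buried_total, buried_per_side (named A/B),
#'   interface_area (= buried_total / 2).
#' @export
buried_area <- function(complex, sel_a, sel_b, ...) {
  ma <- select_atoms(complex, sel_a)
  mb <- select_atoms(complex, sel_b)
  if (n_atoms(ma) == 0 || n_atoms(mb) == 0) stop("empty selection")
  key_a <- with(ma$atoms, paste(chain, resno, insert, elety, alt))
  key_b <- with(mb$atoms, paste(chain, resno, insert, elety, alt))
  if (length(intersect(key_a, key_b)))
    stop("overlapping selections: sel_a and sel_b share atoms")
  sa <- sasa(ma, ...)
  sb <- sasa(mb, ...)
  both <- ma
  both$atoms <- rbind(ma$atoms, mb$atoms)
  sab <- sasa(both, ...)
  na <- length(sa$per_atom)
  buried_a <- sa$total - sum(sab$per_atom[seq_len(na)])
  buried_b <- sb$total - sum(sab$per_atom[-seq_len(na)])
  structure(list(buried_total = buried_a + buried_b,
                 buried_per_side = c(A = buried_a, B = buried_b),
                 interface_area = (buried_a + buried_b) / 2,
                 sasa_a = sa$total, sasa_b = sb$total, sasa_ab = sab$total),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf(paste0("<bsa_result> buried %.1f A^2 total (A: %.1f, B: %.1f); ",
                     "interface area %.1f A^2\n"),
              x$buried_total, x$buried_per_side["A"], x$buried_per_side["B"],
              x$interface_area))
  invisible(x)
}
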