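# Standard base reference frames and Watson-Crick pair detection.
#
# A base_frame is list(origin = 3-vector, axes = 3x3 matrix with columns
# x (toward major groove), y (pairing edge toward the reference sugar),
# z (base normal), right-handed), plus the fit rmsd.

new_base_frame <- function(origin, axes, rmsd = NA_real_, n_atoms = NA_integer_) {
  structure(list(origin = as.numeric(origin), axes = axes,
                 rmsd = rmsd, n_atoms = n_atoms),
            class = "base_frame")
}

#' Fit a standard reference frame to a nucleotide
#'
#' Least-squares superposition (Kabsch) of the embedded idealized base ring
#' geometry onto the observed ring atoms.  The frame is the rigid transform
#' carrying the standard frame onto the observed base.
#'
#' @param res atom table of one DNA/RNA residue (as from a
#'   [structure_model]), or a model containing exactly one residue.
#' @param base override the one-letter base code (default: from the residue
#'   name).
#' @return a `base_frame` with `origin`, `axes`, fit `rmsd` and `n_atoms`.
#' @export
fit_base_frame <- function(res, base = NULL) {
  at <- if (inherits(res, "structure_model")) res$atoms else res
  if (is.null(base)) {
    base <- base_code(at$resid[1])
    if (is.na(base)) stop("cannot infer base code from residue name '",
                          at$resid[1], "'")
  }
  base <- toupper(base)
  if (base %in% c("U", "I"))
    stop("only canonical A/C/G/T bases are supported (got '", base, "')")
  ring <- standard_ring(base)
  obs_idx <- match(rownames(ring), at$elety)
  if (anyNA(obs_idx)) {
    miss <- rownames(ring)[is.na(obs_idx)]
    stop("incomplete base ", at$chain[1], ":", at$resno[1],
         " -- missing ring atom(s): ", paste(miss, collapse = ", "))
  }
  obs <- as.matrix(at[obs_idx, c("x", "y", "z")])
  sp <- kabsch_superpose(ring, obs)
  new_base_frame(origin = sp$translation +
                   as.numeric(sp$rotation %*% c(0, 0, 0)),
                 axes = sp$rotation, rmsd = sp$rmsd, n_atoms = nrow(ring))
}

# Flip a frame to the complementary-strand convention (negate y and z; x is
# shared by the two bases of a Watson-Crick pair).
flip_frame <- function(frame) {
  frame$axes <- frame$axes %*% diag(c(1, -1, -1))
  frame
}

# Average two frames: rotate one halfway toward the other, midpoint origins.
average_frames <- function(f1, f2) {
  R_rel <- f2$axes %*% t(f1$axes)
  axes <- orthonormalize(rotation_power(R_rel, 0.5) %*% f1$axes)
  new_base_frame(origin = (f1$origin + f2$origin) / 2, axes = axes)
}

#' Mid-frame of a base pair
#'
#' The complementary base's frame is flipped (y and z negated), then the two
#' frames are averaged by halving the rotation between them and midpointing
#' the origins.
#'
#' @param frame_ref frame of the reference-strand base.
#' @param frame_comp frame of the complementary base (unflipped).
#' @return a `base_frame`.
#' @export
pair_frame <- function(frame_ref, frame_comp) {
  average_frames(frame_ref, flip_frame(frame_comp))
}

#' Watson-Crick pairing criteria
#'
#' Package defaults for geometric pair detection; the thresholds are design
#' choices (the canonical literature values), all overridable.
#'
#' @param max_da_dist maximum donor-acceptor heavy-atom distance (A).
#' @param min_normal_angle minimum angle between the two base normals
#'   (degrees); antiparallel pairing means close to 180.
#' @param max_origin_dist maximum frame origin-origin distance after the
#'   partner flip (A).
#' @return list of criteria.
#' @export
pair_criteria <- function(max_da_dist = 3.5, min_normal_angle = 140,
                          max_origin_dist = 2.5) {
  list(max_da_dist = max_da_dist, min_normal_angle = min_normal_angle,
       max_origin_dist = max_origin_dist)
}

# Evaluate WC pairing diagnostics for one candidate apposition.  `fB` is the
# partner frame already flipped to the reference convention, so the angle
# between the raw base normals is 180 minus the flipped-normal angle.
# Returns a list with the diagnostics and `paired` (logical).
evaluate_pair <- function(atA, atB, fA, fB, criteria) {
  baseA <- base_code(atA$resid[1]); baseB <- base_code(atB$resid[1])
  complementary <- !is.na(baseA) && !is.na(baseB) &&
    identical(.wc_complement[[baseA]], baseB)
  da <- NA_real_
  if (complementary) {
    hb <- .wc_hbonds[[baseA]]
    dists <- vapply(hb, function(p) {
      ia <- match(p[1], atA$elety); ib <- match(p[2], atB$elety)
      if (is.na(ia) || is.na(ib)) return(Inf)
      vnorm(c(atA$x[ia] - atB$x[ib], atA$y[ia] - atB$y[ib], atA$z[ia] - atB$z[ib]))
    }, numeric(1))
    da <- max(dists)
  }
  normal_angle <- 180 - angle_between(fA$axes[, 3], fB$axes[, 3])
  origin_dist <- vnorm(fA$origin - fB$origin)
  paired <- complementary &&
    is.finite(da) && da <= criteria$max_da_dist &&
    normal_angle >= criteria$min_normal_angle &&
    origin_dist <= criteria$max_origin_dist
  list(paired = paired, complementary = complementary, max_da_dist = da,
       normal_angle = normal_angle, origin_dist = origin_dist)
}

#' Detect Watson-Crick base pairs between two strands
#'
#' Fits a standard frame to every base on both strands and emits a pair for
#' each reference-strand base whose best complementary partner satisfies all
#' criteria: complementary identities, every canonical donor-acceptor
#' distance within `max_da_dist`, near-antiparallel base normals, and frame
#' origins coincident after the partner flip.  Wobble and modified bases are
#' not considered and are skipped with a warning.
#'
#' @param model a [structure_model].
#' @param strand_ref selection expression for the reference strand (5'->3'
#'   along increasing residue number).
#' @param strand_comp selection expression for the complementary strand.
#' @param criteria see [pair_criteria()].
#' @return a `duplex_segment`: list with `positions` (one row per
#'   reference-strand base: paired flag, partner, diagnostics), `pair_frames`
#'   (per-position mid-frames, NULL where unpaired), `ref_frames`,
#'   and the source `model`.
#' @export
detect_base_pairs <- function(model, strand_ref, strand_comp,
                              criteria = pair_criteria()) {
  ref <- select_atoms(model, strand_ref)
  cmp <- select_atoms(model, strand_comp)
  ref_res <- residue_table(ref)
  cmp_res <- residue_table(cmp)
  if (nrow(ref_res) == 0 || nrow(cmp_res) == 0)
    stop("empty strand selection")
  keep_nuc <- function(tbl, label) {
    bad <- !tbl$kind %in% c("dna", "rna") | is.na(base_code(tbl$resid)) |
      base_code(tbl$resid) %in% c("U", "I")
    if (any(bad))
      warning(sum(bad), " non-canonical residue(s) skipped on ", label, " strand")
    tbl[!bad, , drop = FALSE]
  }
  ref_res <- keep_nuc(ref_res, "reference")
  cmp_res <- keep_nuc(cmp_res, "complementary")
  if (nrow(ref_res) < 1 || nrow(cmp_res) < 1) stop("no canonical nucleotides on a strand")

  fit_all <- function(sub_model, tbl) {
    lapply(seq_len(nrow(tbl)), function(i)
      tryCatch(fit_base_frame(residue_atoms(sub_model, tbl$chain[i],
                                            tbl$resno[i], tbl$insert[i])),
               error = function(e) NULL))
  }
  fref <- fit_all(ref, ref_res)
  fcmp <- fit_all(cmp, cmp_res)

  n <- nrow(ref_res)
  pos <- data.frame(
    pos = seq_len(n),
    chain = ref_res$chain, resno = ref_res$resno, insert = ref_res$insert,
    base = base_code(ref_res$resid),
    paired = FALSE,
    partner_chain = NA_character_, partner_resno = NA_integer_,
    partner_insert = NA_character_, partner_base = NA_character_,
    origin_dist = NA_real_, normal_angle = NA_real_, max_da_dist = NA_real_,
    frame_rmsd = vapply(fref, function(f) if (is.null(f)) NA_real_ else f$rmsd,
                        numeric(1)),
    stringsAsFactors = FALSE)
  pair_frames <- vector("list", n)
  taken <- rep(FALSE, nrow(cmp_res))

  for (i in seq_len(n)) {
    if (is.null(fref[[i]])) next
    atA <- residue_atoms(ref, ref_res$chain[i], ref_res$resno[i], ref_res$insert[i])
    best <- NULL; best_j <- NA
    for (j in seq_len(nrow(cmp_res))) {
      if (taken[j] || is.null(fcmp[[j]])) next
      fBflip <- flip_frame(fcmp[[j]])
      # quick origin gate before full diagnostics
      if (vnorm(fref[[i]]$origin - fBflip$origin) > criteria$max_origin_dist + 2) next
      atB <- residue_atoms(cmp, cmp_res$chain[j], cmp_res$resno[j], cmp_res$insert[j])
      ev <- evaluate_pair(atA, atB, fref[[i]], fBflip, criteria)
      if (ev$paired && (is.null(best) || ev$origin_dist < best$origin_dist)) {
        best <- ev; best_j <- j
      }
    }
    if (!is.null(best)) {
      taken[best_j] <- TRUE
      pos$paired[i] <- TRUE
      pos$partner_chain[i] <- cmp_res$chain[best_j]
      pos$partner_resno[i] <- cmp_res$resno[best_j]
      pos$partner_insert[i] <- cmp_res$insert[best_j]
      pos$partner_base[i] <- base_code(cmp_res$resid[best_j])
      pos$origin_dist[i] <- best$origin_dist
      pos$normal_angle[i] <- best$normal_angle
      pos$max_da_dist[i] <- best$max_da_dist
      pair_frames[[i]] <- pair_frame(fref[[i]], fcmp[[best_j]])
    }
  }
  # register hint for unpaired positions on equal-length designed duplexes
  if (nrow(cmp_res) == n) {
    mirror <- n + 1 - pos$pos
    pos$partner_hint_resno <- cmp_res$resno[mirror]
    pos$partner_hint_chain <- cmp_res$chain[mirror]
    pos$partner_hint_insert <- cmp_res$insert[mirror]
  } else {
    pos$partner_hint_resno <- NA_integer_
    pos$partner_hint_chain <- NA_character_
    pos$partner_hint_insert <- NA_character_
  }
  structure(list(positions = pos, pair_frames = pair_frames,
                 ref_frames = fref, model = model,
                 strand_ref = strand_ref, strand_comp = strand_comp,
                 comp_residues = cmp_res, criteria = criteria),
            class = "duplex_segment")
}

#' @export
print.duplex_segment <- function(x, ...) {
  p <- x$positions
  cat("<duplex_segment> ", nrow(p), " reference positions, ",
      sum(p$paired), " paired", sep = "")
  if (any(!p$paired))
    cat(" (unpaired at ", paste(p$pos[!p$paired], collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of detected pairs in a segment
#' @param seg a `duplex_segment`.
#' @export
n_pairs <- function(seg) sum(seg$positions$paired)

#' Export pair diagnostics as TSV
#'
#' @param seg a `duplex_segment`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pair_table <- function(seg, path) {
  utils::write.table(seg$positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Atom table of the residues belonging to position i of a segment: the
# reference base plus its detected partner (or, where unpaired, the
# register-mirror partner on equal-length duplexes).
position_atoms <- function(seg, i, heavy_only = TRUE) {
  p <- seg$positions[i, ]
  at <- residue_atoms(seg$model, p$chain, p$resno, p$insert)
  pc <- if (p$paired) p$partner_chain else p$partner_hint_chain
  pr <- if (p$paired) p$partner_resno else p$partner_hint_resno
  pi <- if (p$paired) p$partner_insert else p$partner_hint_insert
  if (!is.na(pc)) at <- rbind(at, residue_atoms(seg$model, pc, pr, pi))
  if (heavy_only) at <- at[!at$hydrogen, , drop = FALSE]
  at
}
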