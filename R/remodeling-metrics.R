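# Spacer remodeling metrics: end-to-end spacer length, centroid-partition
# kink angle, transcription-bubble size, bundled into a spacer_report.

#' Centroid of a group of atoms
#'
#' Unweighted mean position of all (non-hydrogen, by default) atoms.
#'
#' @param x a [structure_model] or an atom table.
#' @param heavy_only exclude hydrogens (default TRUE).
#' @return 3-vector (A).
#' @export
group_centroid <- function(x, heavy_only = TRUE) {
  xyz <- coords(x, heavy_only = heavy_only)
  if (nrow(xyz) == 0) stop("empty group: no atoms for centroid")
  colMeans(xyz)
}

# Centroid over a set of segment positions.  Three policies:
#  - "all":   unweighted mean over all heavy atoms of both nucleotides of
#             each pair (Chimera-like residue centroid); unpaired positions
#             still contribute their reference base and, on designed
#             equal-length duplexes, the register-mirror partner;
#  - "base":  as "all" but base atoms only (backbone excluded);
#  - "frame": mean of the pair-frame origins (the reference base-frame
#             origin where a pair is broken).  Frame origins lie on the
#             helix axis, so straight DNA reads exactly straight -- atom
#             centroids carry a helical-phase-dependent radial offset.
block_centroid <- function(seg, positions, policy = "all") {
  if (policy == "frame") {
    pts <- vapply(positions, function(i) {
      f <- seg$pair_frames[[i]]
      if (is.null(f)) f <- seg$ref_frames[[i]]
      if (is.null(f)) stop("no frame at position ", i)
      f$origin
    }, numeric(3))
    return(rowMeans(pts))
  }
  at <- do.call(rbind, lapply(positions, position_atoms, seg = seg))
  if (policy == "base") {
    bb <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
            "C2'", "C1'")
    at <- at[!at$elety %in% bb, , drop = FALSE]
  }
  group_centroid(at)
}

#' Spacer length: centroid-to-centroid distance of the terminal base pairs
#'
#' @param seg a `duplex_segment`.
#' @param atom_policy centroid policy: "all" (default, all heavy atoms of
#'   both nucleotides -- Chimera-like residue centroids), "base" (base atoms
#'   only) or "frame" (pair-frame origins).
#' @return distance in A.
#' @export
spacer_length <- function(seg, atom_policy = c("all", "base", "frame")) {
  atom_policy <- match.arg(atom_policy)
  p <- seg$positions
  n <- nrow(p)
  if (n < 2) stop("need at least 2 positions")
  if (!p$paired[1] || !p$paired[n])
    stop("terminal pair broken; select the intact pair range explicitly")
  c1 <- block_centroid(seg, 1, policy = atom_policy)
  c2 <- block_centroid(seg, n, policy = atom_policy)
  vnorm(c2 - c1)
}

# Default three-block partition: central 7 base pairs, flanks split evenly
# (6/7/6 for 19 bp, 5/7/5 for 17 bp).
auto_partition <- function(n) {
  if (n < 9) stop("too few base pairs (", n, ") for a three-block partition")
  fl <- n - 7
  if (fl %% 2 != 0)
    stop("no symmetric partition with a central 7-bp block for ", n,
         " bp; give partition explicitly")
  c(fl / 2, 7, fl / 2)
}

#' Kink angle of a spacer
#'
#' Partitions the spacer into three blocks of base pairs (by default the
#' central seven with the flanks split evenly, i.e. 6/7/6 for 19 bp and
#' 5/7/5 for 17 bp), takes the centroid of each block, and reports the
#' deviation from collinearity: 180 degrees minus the interior angle at the
#' central centroid.  Straight DNA reads 0.
#'
#' @param seg a `duplex_segment`.
#' @param partition integer 3-vector summing to the position count, or NULL
#'   for the automatic partition.
#' @param atom_policy block-centroid policy; the default "frame" (pair-frame
#'   origins) puts the block centroids on the helix axis, so straight DNA
#'   reads 0 exactly; "all"/"base" atom centroids carry a small
#'   helical-phase artifact of a few degrees on straight DNA.
#' @return kink angle in degrees, in \[0, 180\].
#' @export
kink_angle <- function(seg, partition = NULL,
                       atom_policy = c("frame", "all", "base")) {
  atom_policy <- match.arg(atom_policy)
  n <- nrow(seg$positions)
  if (is.null(partition)) partition <- auto_partition(n)
  if (length(partition) != 3 || any(partition < 1))
    stop("partition must be three positive block sizes")
  if (sum(partition) != n)
    stop("partition sums to ", sum(partition), " but the spacer has ", n, " bp")
  b1 <- seq_len(partition[1])
  b2 <- partition[1] + seq_len(partition[2])
  b3 <- partition[1] + partition[2] + seq_len(partition[3])
  c1 <- block_centroid(seg, b1, policy = atom_policy)
  c2 <- block_centroid(seg, b2, policy = atom_policy)
  c3 <- block_centroid(seg, b3, policy = atom_policy)
  v1 <- c1 - c2; v2 <- c3 - c2
  if (vnorm(v1) < 1e-6 || vnorm(v2) < 1e-6)
    stop("degenerate partition: coincident block centroids")
  180 - angle_between(v1, v2)
}

#' Transcription-bubble size
#'
#' The longest run of consecutive reference-strand (template) positions
#' with no Watson-Crick DNA partner, bounded on both sides by intact pairs.
#' The count of unpartnered complementary-strand (non-template) nucleotides
#' between the bounding pairs is reported alongside.  A run touching the
#' segment edge triggers an open-ended-bubble warning but is still
#' reported.
#'
#' @param seg a `duplex_segment` computed over the full scaffold.
#' @return list with `size` (template-strand count), `nt_size`
#'   (non-template count), `start`, `end` (reference positions), and
#'   `open_ended`.
#' @export
bubble_size <- function(seg) {
  p <- seg$positions
  r <- rle(!p$paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs))
    return(list(size = 0L, nt_size = 0L, start = NA_integer_,
                end = NA_integer_, open_ended = FALSE))
  k <- runs[which.max(r$lengths[runs])]
  s <- starts[k]; e <- ends[k]
  open_ended <- s == 1 || e == nrow(p)
  if (open_ended)
    warning("open-ended bubble: unpaired run touches the segment edge")
  # non-template count between the partners of the bounding pairs
  nt_size <- NA_integer_
  cmp <- seg$comp_residues
  if (!is.null(cmp) && nrow(cmp)) {
    partnered <- paste(p$partner_chain, p$partner_resno, p$partner_insert)[p$paired]
    cmp_key <- paste(cmp$chain, cmp$resno, cmp$insert)
    lo_idx <- if (s > 1) match(paste(p$partner_chain[s - 1], p$partner_resno[s - 1],
                                     p$partner_insert[s - 1]), cmp_key) else NA
    hi_idx <- if (e < nrow(p)) match(paste(p$partner_chain[e + 1], p$partner_resno[e + 1],
                                           p$partner_insert[e + 1]), cmp_key) else NA
    rng <- if (!is.na(lo_idx) && !is.na(hi_idx)) {
      seq(min(lo_idx, hi_idx) + 1, max(lo_idx, hi_idx) - 1)
    } else seq_len(nrow(cmp))
    if (length(rng))
      nt_size <- sum(!cmp_key[rng] %in% partnered)
    else nt_size <- 0L
  }
  list(size = as.integer(e - s + 1), nt_size = as.integer(nt_size),
       start = as.integer(s), end = as.integer(e), open_ended = open_ended)
}

#' Full spacer remodeling report
#'
#' Runs pair detection, frame fitting, step parameters, spacer length, kink
#' angle, the twist summary and the bubble size for one spacer, and bundles
#' them.  Deterministic given the model and options.
#'
#' @param model a [structure_model].
#' @param t_strand selection expression for the template strand (the
#'   reference strand, 5'->3').
#' @param nt_strand selection expression for the non-template strand.
#' @param partition kink partition (NULL = automatic).
#' @param extrapolation_steps,ideal_twist_per_step see
#'   [spacer_total_twist()].
#' @param criteria pairing criteria, see [pair_criteria()].
#' @param kink_policy block-centroid policy for the kink angle (default
#'   "frame"; see [kink_angle()]).
#' @param length_policy centroid policy for the spacer length (default
#'   "all"; see [spacer_length()]).
#' @return a `spacer_report`.
#' @export
spacer_report <- function(model, t_strand, nt_strand, partition = NULL,
                          extrapolation_steps = 19, ideal_twist_per_step = 36.0,
                          criteria = pair_criteria(), kink_policy = "frame",
                          length_policy = "all") {
  seg <- detect_base_pairs(model, t_strand, nt_strand, criteria = criteria)
  p <- seg$positions
  n <- nrow(p)
  L <- tryCatch(spacer_length(seg, atom_policy = length_policy),
                error = function(e) NA_real_)
  part <- if (is.null(partition)) tryCatch(auto_partition(n), error = function(e) NULL)
          else partition
  theta <- if (is.null(part)) NA_real_
           else kink_angle(seg, partition = part, atom_policy = kink_policy)
  tw <- tryCatch(spacer_total_twist(seg, extrapolation_steps = extrapolation_steps,
                                    ideal_twist_per_step = ideal_twist_per_step),
                 error = function(e) NULL)
  bub <- withCallingHandlers(bubble_size(seg),
                             warning = function(w) invokeRestart("muffleWarning"))
  structure(list(spacer_length = L, kink_angle = theta,
                 partition = part, twist = tw,
                 bubble_size = bub$size, bubble = bub,
                 n_pairs = sum(p$paired), n_unpaired = sum(!p$paired),
                 n_positions = n, segment = seg),
            class = "spacer_report")
}

#' @export
print.spacer_report <- function(x, ...) {
  cat("<spacer_report> ", x$n_positions, " bp (", x$n_pairs, " paired, ",
      x$n_unpaired, " unpaired)\n", sep = "")
  cat(sprintf("  spacer length L = %.1f A\n", x$spacer_length))
  if (!is.na(x$kink_angle))
    cat(sprintf("  kink angle = %.1f deg (partition %s)\n", x$kink_angle,
                paste(x$partition, collapse = "/")))
  if (!is.null(x$twist))
    cat(sprintf("  mean h-twist %.2f deg/step (%d steps) -> total %.1f deg, under-twist %.1f deg\n",
                x$twist$mean_h_twist, x$twist$n_steps_used,
                x$twist$total_twist, x$twist$under_twist))
  cat("  bubble size:", x$bubble_size, "nt\n")
  invisible(x)
}

# Flat named list of the report's scalar metrics (for JSON / TSV export).
report_values <- function(report) {
  list(n_positions = report$n_positions, n_pairs = report$n_pairs,
       n_unpaired = report$n_unpaired,
       spacer_length = report$spacer_length,
       kink_angle = report$kink_angle,
       partition = paste(report$partition, collapse = "/"),
       mean_h_twist = if (is.null(report$twist)) NA else report$twist$mean_h_twist,
       n_steps_used = if (is.null(report$twist)) NA else report$twist$n_steps_used,
       total_twist = if (is.null(report$twist)) NA else report$twist$total_twist,
       under_twist = if (is.null(report$twist)) NA else report$twist$under_twist,
       bubble_size = report$bubble_size)
}

#' Serialize a spacer report
#'
#' @param report a `spacer_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_values(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, path) {
  v <- report_values(report)
  utils::write.table(data.frame(metric = names(v),
                                value = vapply(v, as.character, character(1))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
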