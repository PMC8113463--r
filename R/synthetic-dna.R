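# Deterministic B-DNA duplex generator driven by per-step parameter
# schedules, with controllable kinks (roll spikes), global unwinding and
# opened base pairs.  Every build carries a machine-readable ground-truth
# record so the analysis chain can be tested end to end without downloads.

#' Step-parameter schedule for a duplex build
#'
#' One row per base-pair step; values recycle over steps.  The default
#' schedule is ideal B-form DNA: twist 36.0 deg/step (10.0 bp/turn), rise
#' 3.38 A, all other parameters zero.
#'
#' @param sequence reference-strand base string over A/C/G/T (5'->3').
#' @param twist,rise,roll,tilt,shift,slide per-step values (recycled).
#' @return a `step_schedule`: data.frame of steps with the sequence as an
#'   attribute.
#' @export
step_schedule <- function(sequence, twist = 36.0, rise = 3.38, roll = 0,
                          tilt = 0, shift = 0, slide = 0) {
  sequence <- toupper(gsub("\\s", "", sequence))
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) == 0) stop("empty sequence")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad)) stop("invalid base letter(s): ", paste(bad, collapse = ", "))
  ns <- length(bases) - 1
  sch <- data.frame(shift = rep_len(shift, ns), slide = rep_len(slide, ns),
                    rise = rep_len(rise, ns), tilt = rep_len(tilt, ns),
                    roll = rep_len(roll, ns), twist = rep_len(twist, ns))
  if (ns > 0 && any(sch$rise <= 0)) stop("rise must be positive")
  structure(sch, sequence = sequence, class = c("step_schedule", "data.frame"))
}

schedule_sequence <- function(schedule) attr(schedule, "sequence")

#' Add a localized kink (roll spike) to a schedule
#'
#' Adds `roll_delta` degrees of roll at step `position`, optionally spread
#' evenly over `width` consecutive steps.  The ground-truth global bend this
#' induces (the angle between the entry and exit helical axes, computed
#' analytically from the composed step rotations) is recorded on the
#' schedule.
#'
#' @param schedule a [step_schedule()].
#' @param position step index (1-based) of the (first) kinked step.
#' @param roll_delta added roll in degrees; |roll_delta| must be <= 90.
#' @param width number of consecutive steps to spread the roll over.
#' @return the modified `step_schedule`.
#' @export
impose_kink <- function(schedule, position, roll_delta, width = 1) {
  if (abs(roll_delta) > 90)
    stop("|roll_delta| > 90 degrees rejected as unphysical")
  idx <- position + seq_len(width) - 1
  if (any(idx < 1 | idx > nrow(schedule))) stop("kink position out of range")
  schedule$roll[idx] <- schedule$roll[idx] + roll_delta / width
  attr(schedule, "kink") <- list(position = position, roll_delta = roll_delta,
                                 width = width,
                                 bend = schedule_bend(schedule),
                                 centroid_kink = tryCatch(schedule_kink(schedule),
                                                          error = function(e) NA_real_))
  schedule
}

#' Impose a kink that reads a target centroid-partition kink angle
#'
#' The block-centroid kink convention reads a localized bend lower than the
#' underlying axis bend (the central block centroid is pulled into the
#' wedge), so a roll spike of X degrees does not produce a centroid kink of
#' X degrees.  This helper solves, in closed form on the composed step
#' rotations, for the roll spike whose *centroid-method* kink equals
#' `target_kink`, and imposes it.
#'
#' @param schedule a [step_schedule()].
#' @param position step index of the kinked step.
#' @param target_kink desired centroid-partition kink angle (degrees).
#' @param partition kink partition (NULL = automatic).
#' @param width steps to spread the roll over.
#' @return the modified `step_schedule` (ground truth records both the roll
#'   spike found and the analytic bend).
#' @export
impose_centroid_kink <- function(schedule, position, target_kink,
                                 partition = NULL, width = 1) {
  f <- function(delta) {
    s <- schedule
    idx <- position + seq_len(width) - 1
    s$roll[idx] <- s$roll[idx] + delta / width
    schedule_kink(s, partition) - target_kink
  }
  if (f(0) >= 0) stop("schedule already kinked beyond the target")
  sol <- stats::uniroot(f, c(0, 90), tol = 1e-8)
  impose_kink(schedule, position, sol$root, width = width)
}

# Pair frames of a schedule, composed analytically (no atoms).
schedule_frames <- function(schedule) {
  n <- nrow(schedule) + 1
  frames <- vector("list", n)
  frames[[1]] <- new_base_frame(c(0, 0, 0), diag(3))
  for (i in seq_len(nrow(schedule)))
    frames[[i + 1]] <- step_transform(frames[[i]],
                                      schedule$shift[i], schedule$slide[i],
                                      schedule$rise[i], schedule$tilt[i],
                                      schedule$roll[i], schedule$twist[i])
  frames
}

# Analytic global bend of a schedule: the angle between the z-axes of the
# first and last pair frames under the composed step rotations.
schedule_bend <- function(schedule) {
  fr <- schedule_frames(schedule)
  angle_between(fr[[1]]$axes[, 3], fr[[length(fr)]]$axes[, 3])
}

# Analytic centroid-partition kink of a schedule: composes the pair frames,
# takes the three block centroids of their origins, and returns 180 minus
# the interior angle -- the same convention the analyzer applies to fitted
# frames, evaluated in closed form on the schedule.
schedule_kink <- function(schedule, partition = NULL) {
  fr <- schedule_frames(schedule)
  org <- t(vapply(fr, function(f) f$origin, numeric(3)))
  n <- nrow(org)
  if (is.null(partition)) partition <- auto_partition(n)
  b1 <- seq_len(partition[1])
  b2 <- partition[1] + seq_len(partition[2])
  b3 <- partition[1] + partition[2] + seq_len(partition[3])
  c1 <- colMeans(org[b1, , drop = FALSE])
  c2 <- colMeans(org[b2, , drop = FALSE])
  c3 <- colMeans(org[b3, , drop = FALSE])
  180 - angle_between(c1 - c2, c3 - c2)
}

#' Unwind a schedule by a total under-twist
#'
#' Subtracts `total_under_twist / n_ref_steps` degrees uniformly from every
#' step's twist (the uniform-unwinding model of regulator-imposed spacer
#' under-twisting).
#'
#' @param schedule a [step_schedule()].
#' @param total_under_twist total unwinding in degrees over the reference
#'   step count.
#' @param n_ref_steps reference step count the total is spread over
#'   (default 19).
#' @return the modified `step_schedule`.
#' @export
impose_unwinding <- function(schedule, total_under_twist, n_ref_steps = 19) {
  per_step <- total_under_twist / n_ref_steps
  new_twist <- schedule$twist - per_step
  if (any(new_twist <= 0))
    stop("over-unwinding: per-step twist would become non-positive")
  schedule$twist <- new_twist
  attr(schedule, "under_twist") <- list(total = total_under_twist,
                                        n_ref_steps = n_ref_steps,
                                        per_step = per_step)
  schedule
}

#' Build an atomic B-DNA duplex from a schedule
#'
#' Places idealized standard-geometry base pairs by composing mid-step-frame
#' transforms (the exact inverse of the [step_parameters()] convention),
#' with decorative idealized sugar-phosphate atoms attached in each base
#' frame.  Deterministic: identical schedules give bit-identical
#' coordinates.  The reference (template) strand is chain A numbered 1..n
#' 5'->3'; the complementary strand is chain B numbered 1..n in its own
#' 5'->3' direction (B residue j pairs with A residue n+1-j).
#'
#' @param schedule a [step_schedule()].
#' @param backbone attach the decorative sugar-phosphate template atoms.
#' @param entry_id id stored on the model.
#' @return list with `model` (a [structure_model]) and `truth` (ground
#'   truth: the schedule as built, per-pair frames as placed, imposed kink /
#'   under-twist records, broken-pair positions).
#' @export
build_duplex <- function(schedule, backbone = TRUE, entry_id = "synthetic_duplex") {
  seq_ref <- schedule_sequence(schedule)
  bases <- strsplit(seq_ref, "")[[1]]
  n <- length(bases)
  frames <- vector("list", n)
  frames[[1]] <- new_base_frame(c(0, 0, 0), diag(3))
  for (i in seq_len(n - 1))
    frames[[i + 1]] <- step_transform(frames[[i]],
                                      schedule$shift[i], schedule$slide[i],
                                      schedule$rise[i], schedule$tilt[i],
                                      schedule$roll[i], schedule$twist[i])
  flipper <- diag(c(1, -1, -1))
  place <- function(frame_axes, origin, std) {
    sweep(std %*% t(frame_axes), 2, origin, "+")
  }
  rows <- list()
  add_residue <- function(chain, resno, base, xyz_mat) {
    data.frame(chain = chain, resno = resno, insert = "",
               resid = paste0("D", base), elety = rownames(xyz_mat),
               element = guess_element(rownames(xyz_mat)),
               alt = "", x = xyz_mat[, 1], y = xyz_mat[, 2], z = xyz_mat[, 3],
               occ = 1, b = 0, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    std <- standard_base(bases[i], backbone = backbone)
    rows[[length(rows) + 1]] <-
      add_residue("A", i, bases[i],
                  place(frames[[i]]$axes, frames[[i]]$origin, std))
  }
  comp <- .wc_complement[bases]
  for (j in seq_len(n)) {
    i <- n + 1 - j  # pair position on the reference strand
    std <- standard_base(comp[i], backbone = backbone)
    axes_b <- frames[[i]]$axes %*% flipper
    rows[[length(rows) + 1]] <-
      add_residue("B", j, comp[i], place(axes_b, frames[[i]]$origin, std))
  }
  atoms <- do.call(rbind, rows)
  model <- structure_model(atoms, entry_id = entry_id,
                           provenance = list(format = "synthetic"))
  truth <- list(sequence = seq_ref,
                schedule = as.data.frame(schedule),
                kink = attr(schedule, "kink"),
                under_twist = attr(schedule, "under_twist"),
                pair_frames = frames,
                broken = integer(0),
                seed = attr(schedule, "seed"))
  list(model = model, truth = truth)
}

#' Open base pairs in a built duplex (transcription-bubble fixture)
#'
#' Displaces the complementary (non-template) base of each listed pair
#' position along the pair x-axis so that every pairing criterion fails, and
#' records the broken positions in the ground truth.
#'
#' @param duplex list(model, truth) from [build_duplex()].
#' @param positions reference-strand pair positions (1-based) to open.
#' @param displacement displacement along the pair x-axis in A (>= 6
#'   guarantees failure of all default criteria).
#' @return the modified list(model, truth).
#' @export
open_bubble <- function(duplex, positions, displacement = 8) {
  if (!length(positions)) return(duplex)
  model <- duplex$model
  truth <- duplex$truth
  n <- nchar(truth$sequence)
  if (any(positions < 1 | positions > n)) stop("bubble position out of range")
  for (p in positions) {
    j <- n + 1 - p  # chain B residue number pairing with position p
    frame <- truth$pair_frames[[p]]
    shift_vec <- frame$axes[, 1] * displacement
    sel <- model$atoms$chain == "B" & model$atoms$resno == j
    model$atoms$x[sel] <- model$atoms$x[sel] + shift_vec[1]
    model$atoms$y[sel] <- model$atoms$y[sel] + shift_vec[2]
    model$atoms$z[sel] <- model$atoms$z[sel] + shift_vec[3]
  }
  truth$broken <- sort(unique(c(truth$broken, as.integer(positions))))
  list(model = model, truth = truth)
}

#' Write a ground-truth record as JSON
#'
#' @param truth the `truth` component of a built duplex.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$pair_frames <- lapply(out$pair_frames, function(f)
    list(origin = f$origin, axes = f$axes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Random step schedule (for property tests)
#'
#' Uniform draws within physically mild ranges; the seed is recorded so
#' builds are reproducible.
#'
#' @param n_bp number of base pairs.
#' @param seed integer seed.
#' @param twist_range,roll_range,tilt_range,rise_range sampling ranges.
#' @return a `step_schedule` with the seed attached.
#' @export
random_schedule <- function(n_bp, seed,
                            twist_range = c(25, 40), roll_range = c(-15, 15),
                            tilt_range = c(-15, 15), rise_range = c(3.1, 3.6)) {
  set.seed(seed)
  ns <- n_bp - 1
  sequence <- paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE),
                    collapse = "")
  sch <- step_schedule(sequence,
                       twist = stats::runif(ns, twist_range[1], twist_range[2]),
                       rise = stats::runif(ns, rise_range[1], rise_range[2]),
                       roll = stats::runif(ns, roll_range[1], roll_range[2]),
                       tilt = stats::runif(ns, tilt_range[1], tilt_range[2]),
                       shift = stats::runif(ns, -0.5, 0.5),
                       slide = stats::runif(ns, -0.5, 0.5))
  attr(sch, "seed") <- seed
  sch
}
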