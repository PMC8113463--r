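# Base-pair step parameters in the CEHS / mid-step-frame scheme, plus the
# helical set defined about the local helical axis, and the spacer-level
# twist summary (total twist and under-twist against ideal B-form DNA).

#' Base-pair step parameters between two pair frames
#'
#' CEHS (mid-step frame) scheme: the roll-tilt hinge is the common normal of
#' the two z-axes; each frame is rotated half the bending angle toward the
#' other so the z-axes merge, twist is measured between the y-axes about the
#' merged z, and (shift, slide, rise) are the origin difference in mid-step
#' axes.  The helical set comes from the axis-angle decomposition of the
#' full inter-frame rotation: h-twist is the rotation angle about the local
#' helical axis, h-rise the translation along it, x/y-displacement the
#' perpendicular offset of the frame origin from the axis, and
#' inclination/tip the orientation of the axis in mid-step coordinates.
#'
#' @param f1,f2 `base_frame` objects for consecutive base pairs (5'->3').
#' @return one-row data.frame with shift, slide, rise, tilt, roll, twist,
#'   x_disp, y_disp, h_rise, inclination, tip, h_twist.
#' @export
step_parameters <- function(f1, f2) {
  R1 <- f1$axes; R2 <- f2$axes
  o1 <- f1$origin; o2 <- f2$origin
  z1 <- R1[, 3]; z2 <- R2[, 3]

  gamma <- angle_between(z1, z2)
  if (gamma > 179)
    warning("near-180 degree inter-frame rotation; step parameters are ill-conditioned")
  cr <- cross3(z1, z2)
  if (vnorm(cr) < 1e-9) {
    hinge <- R1[, 2]  # any axis perpendicular to z works when z1 == z2
    gamma <- 0
  } else {
    hinge <- unit(cr)
  }
  R1p <- rotation_about(hinge, gamma / 2) %*% R1
  R2p <- rotation_about(hinge, -gamma / 2) %*% R2
  zm <- unit(R1p[, 3] + R2p[, 3])
  twist <- signed_angle(R1p[, 2], R2p[, 2], zm)
  ym <- unit(R1p[, 2] + R2p[, 2])
  xm <- unit(cross3(ym, zm))
  Rm <- cbind(xm, ym, zm)
  d <- as.numeric(t(Rm) %*% (o2 - o1))
  phi <- atan2(sum(hinge * xm), sum(hinge * ym))
  roll <- gamma * cos(phi)
  tilt <- gamma * sin(phi)

  # helical set from the full inter-frame rotation
  Rrel <- R2 %*% t(R1)
  aa <- axis_angle(Rrel)
  # orient the helical axis along the mid-step z, so right-handed DNA has
  # positive h-twist
  if (sum(aa$axis * zm) < 0) {
    n <- -aa$axis
    h_twist <- -aa$angle
  } else {
    n <- aa$axis
    h_twist <- aa$angle
  }
  h_rise <- sum((o2 - o1) * n)
  if (aa$angle < 1e-7) {
    x_disp <- y_disp <- 0
    inclination <- tip <- 0
  } else {
    # fixed point of the screw transformation in the plane perpendicular to n
    rhs <- (o2 - h_rise * n) - Rrel %*% o1
    A <- diag(3) - Rrel
    p <- tryCatch({
      sv <- svd(A)
      dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
      as.numeric(sv$v %*% (dinv * (t(sv$u) %*% rhs)))
    }, error = function(e) rep(NA_real_, 3))
    dvec <- (o1 - p)
    dvec <- dvec - sum(dvec * n) * n
    x_disp <- sum(dvec * xm)
    y_disp <- sum(dvec * ym)
    nm <- as.numeric(t(Rm) %*% n)
    inclination <- atan2(nm[2], nm[3]) * DEG
    tip <- atan2(nm[1], nm[3]) * DEG
  }
  data.frame(shift = d[1], slide = d[2], rise = d[3],
             tilt = tilt, roll = roll, twist = twist,
             x_disp = x_disp, y_disp = y_disp, h_rise = h_rise,
             inclination = inclination, tip = tip, h_twist = h_twist)
}

# Inverse of step_parameters: given frame f1 and scheduled
# (shift, slide, rise, tilt, roll, twist), construct frame f2 such that the
# CEHS decomposition of (f1, f2) returns the schedule exactly.
step_transform <- function(f1, shift = 0, slide = 0, rise = 3.38,
                           tilt = 0, roll = 0, twist = 36) {
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll) * DEG
  Rz <- function(a) rotation_about(c(0, 0, 1), a)
  Ry <- function(a) rotation_about(c(0, 1, 0), a)
  Rrel_local <- Rz(twist / 2 - phi) %*% Ry(gamma) %*% Rz(twist / 2 + phi)
  R2 <- f1$axes %*% Rrel_local
  f2 <- new_base_frame(origin = f1$origin, axes = orthonormalize(R2))
  # mid-step frame recomputed exactly as the analyzer does
  mids <- mid_step_axes(f1$axes, f2$axes)
  f2$origin <- f1$origin + as.numeric(mids %*% c(shift, slide, rise))
  f2
}

# Mid-step axes (xm, ym, zm) for two pair frames, CEHS construction.
mid_step_axes <- function(R1, R2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cr <- cross3(z1, z2)
  if (vnorm(cr) < 1e-9) {
    hinge <- R1[, 2]
    gamma <- 0
  } else {
    hinge <- unit(cr)
    gamma <- angle_between(z1, z2)
  }
  R1p <- rotation_about(hinge, gamma / 2) %*% R1
  R2p <- rotation_about(hinge, -gamma / 2) %*% R2
  zm <- unit(R1p[, 3] + R2p[, 3])
  ym <- unit(R1p[, 2] + R2p[, 2])
  xm <- unit(cross3(ym, zm))
  cbind(xm, ym, zm)
}

#' Per-step parameter table for a duplex segment
#'
#' One row per step between consecutive detected pairs whose
#' reference-strand positions differ by 1; steps spanning an unpaired
#' position are excluded (frames at broken pairs are unreliable).
#'
#' @param seg a `duplex_segment` from [detect_base_pairs()].
#' @param include_broken also emit steps spanning unpaired positions.
#' @return data.frame with `step` (reference position of the 5' pair) and
#'   the twelve step/helical parameters.
#' @export
step_parameter_table <- function(seg, include_broken = FALSE) {
  p <- seg$positions
  rows <- list()
  for (i in seq_len(nrow(p) - 1)) {
    ok <- p$paired[i] && p$paired[i + 1]
    if (!ok && !include_broken) next
    if (is.null(seg$pair_frames[[i]]) || is.null(seg$pair_frames[[i + 1]])) next
    sp <- step_parameters(seg$pair_frames[[i]], seg$pair_frames[[i + 1]])
    sp <- cbind(data.frame(step = i), sp)
    rows[[length(rows) + 1]] <- sp
  }
  if (!length(rows))
    return(cbind(data.frame(step = integer(0)),
                 step_parameters(new_base_frame(c(0, 0, 0), diag(3)),
                                 new_base_frame(c(0, 0, 0), diag(3)))[0, ]))
  do.call(rbind, rows)
}

#' Export a step-parameter table as TSV
#'
#' W3DNA-style column names (Shift, Slide, Rise, Tilt, Roll, Twist, X-disp,
#' Y-disp, h-Rise, Incl., Tip, h-Twist).
#'
#' @param steps data.frame from [step_parameter_table()].
#' @param path output file.
#' @export
write_step_table <- function(steps, path) {
  out <- steps
  names(out) <- c("Step", "Shift", "Slide", "Rise", "Tilt", "Roll", "Twist",
                  "X-disp", "Y-disp", "h-Rise", "Incl.", "Tip", "h-Twist")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total spacer twist by h-twist extrapolation
#'
#' Averages the helical twist (h-twist) over all measured steps and
#' extrapolates the mean over `extrapolation_steps` steps; the under-twist
#' is the ideal B-form total minus the extrapolated total (positive =
#' unwound).
#'
#' @param seg a `duplex_segment`.
#' @param extrapolation_steps number of steps the mean is extrapolated over
#'   (default 19, the spacer base-pair count convention).
#' @param ideal_twist_per_step ideal B-form twist per step, degrees
#'   (default 36.0, i.e. 10.0 bp/turn).
#' @return a `twist_summary`: mean_h_twist, n_steps_used,
#'   extrapolation_steps, total_twist, ideal_total, under_twist.
#' @export
spacer_total_twist <- function(seg, extrapolation_steps = 19,
                               ideal_twist_per_step = 36.0) {
  steps <- step_parameter_table(seg)
  if (nrow(steps) == 0)
    stop("insufficient pairs: no valid consecutive steps in segment")
  mean_h <- mean(steps$h_twist)
  total <- mean_h * extrapolation_steps
  ideal <- ideal_twist_per_step * extrapolation_steps
  structure(list(mean_h_twist = mean_h, n_steps_used = nrow(steps),
                 extrapolation_steps = extrapolation_steps,
                 total_twist = total, ideal_total = ideal,
                 under_twist = ideal - total,
                 ideal_twist_per_step = ideal_twist_per_step),
            class = "twist_summary")
}

#' @export
print.twist_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<twist_summary> mean h-twist %.2f deg/step over %d step(s)\n",
    "  total twist %.1f deg over %d steps (ideal %.1f) -> under-twist %.1f deg\n"),
    x$mean_h_twist, x$n_steps_used, x$total_twist, x$extrapolation_steps,
    x$ideal_total, x$under_twist))
  invisible(x)
}

#' Under-twist of a spacer relative to ideal B-form DNA
#'
#' @param summary a `twist_summary` from [spacer_total_twist()].
#' @param ideal_twist_per_step ideal B-form twist per step (degrees).
#' @return under-twist in degrees (positive = unwound).
#' @export
under_twist <- function(summary, ideal_twist_per_step = 36.0) {
  ideal_twist_per_step * summary$extrapolation_steps - summary$total_twist
}
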