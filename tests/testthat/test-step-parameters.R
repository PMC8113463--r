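ident_frame <- function() list(origin = c(0, 0, 0), axes = diag(3))

test_that("a pure helical step has the closed-form parameters", {
  f1 <- ident_frame()
  f2 <- list(origin = c(0, 0, 3.40),
             axes = rotation_about(c(0, 0, 1), 36))
  p <- step_parameters(f1, f2)
  expect_equal(p$twist, 36, tolerance = 1e-9)
  expect_equal(p$rise, 3.40, tolerance = 1e-9)
  expect_equal(p$h_twist, 36, tolerance = 1e-9)
  expect_equal(p$h_rise, 3.40, tolerance = 1e-9)
  expect_equal(p$tilt, 0, tolerance = 1e-9)
  expect_equal(p$roll, 0, tolerance = 1e-9)
  expect_equal(p$x_disp, 0, tolerance = 1e-6)
  expect_equal(p$y_disp, 0, tolerance = 1e-6)
  expect_equal(p$inclination, 0, tolerance = 1e-6)
  expect_equal(p$tip, 0, tolerance = 1e-6)
})

test_that("the identity step has all parameters zero", {
  p <- step_parameters(ident_frame(), ident_frame())
  expect_true(all(abs(unlist(p)) < 1e-9))
})

test_that("scheduled step parameters are recovered from constructed frames", {
  cases <- expand.grid(tilt = c(-4, 0, 4), roll = c(-5, 0, 10),
                       twist = c(28, 36))
  for (k in seq_len(nrow(cases))) {
    f1 <- ident_frame()
    f2 <- spacergeom:::step_transform(f1, shift = 0.3, slide = -0.4,
                                      rise = 3.3, tilt = cases$tilt[k],
                                      roll = cases$roll[k],
                                      twist = cases$twist[k])
    p <- step_parameters(f1, f2)
    expect_equal(p$tilt, cases$tilt[k], tolerance = 1e-8)
    expect_equal(p$roll, cases$roll[k], tolerance = 1e-8)
    expect_equal(p$twist, cases$twist[k], tolerance = 1e-8)
    expect_equal(p$shift, 0.3, tolerance = 1e-8)
    expect_equal(p$slide, -0.4, tolerance = 1e-8)
    expect_equal(p$rise, 3.3, tolerance = 1e-8)
  }
})

test_that("h-twist equals the eigen-decomposition rotation angle", {
  for (seed in 1:20) {
    R1 <- random_rotation(seed)
    R2 <- random_rotation(seed + 100)
    f1 <- list(origin = random_translation(seed), axes = R1)
    f2 <- list(origin = random_translation(seed + 100), axes = R2)
    p <- suppressWarnings(step_parameters(f1, f2))
    oracle <- eigen_rotation_angle(R2 %*% t(R1))
    expect_equal(abs(p$h_twist), oracle, tolerance = 1e-6)
  }
})

test_that("step parameters are invariant under rigid motion", {
  f1 <- ident_frame()
  f2 <- spacergeom:::step_transform(f1, shift = 0.2, slide = 0.1, rise = 3.4,
                                    tilt = 3, roll = 8, twist = 33)
  p0 <- step_parameters(f1, f2)
  R <- random_rotation(21); tr <- random_translation(21)
  move <- function(f) list(origin = as.numeric(R %*% f$origin + tr),
                           axes = R %*% f$axes)
  p1 <- step_parameters(move(f1), move(f2))
  expect_equal(unlist(p1), unlist(p0), tolerance = 1e-8)
})

test_that("reversing the duplex direction negates tilt and keeps twist/rise", {
  f1 <- ident_frame()
  f2 <- spacergeom:::step_transform(f1, tilt = 6, roll = 7, twist = 32,
                                    rise = 3.2, shift = 0.25, slide = -0.15)
  fwd <- step_parameters(f1, f2)
  flip <- function(f) list(origin = f$origin,
                           axes = f$axes %*% diag(c(1, -1, -1)))
  rev <- step_parameters(flip(f2), flip(f1))
  expect_equal(rev$twist, fwd$twist, tolerance = 1e-8)
  expect_equal(rev$rise, fwd$rise, tolerance = 1e-8)
  expect_equal(rev$roll, fwd$roll, tolerance = 1e-8)
  expect_equal(rev$tilt, -fwd$tilt, tolerance = 1e-8)
  expect_equal(rev$shift, -fwd$shift, tolerance = 1e-8)
  expect_equal(rev$slide, fwd$slide, tolerance = 1e-8)
})

test_that("total spacer twist extrapolates the mean h-twist", {
  d <- build_duplex(step_schedule(strrep("A", 19)))
  seg <- detect_base_pairs(d$model, "A", "B")
  tw <- spacer_total_twist(seg)
  expect_equal(tw$n_steps_used, 18)
  expect_equal(tw$total_twist, 684.0, tolerance = 0.1)
  expect_equal(tw$under_twist, 0, tolerance = 0.1)

  d2 <- build_duplex(step_schedule(strrep("A", 19), twist = 31.7))
  tw2 <- spacer_total_twist(detect_base_pairs(d2$model, "A", "B"))
  expect_equal(tw2$total_twist, 602.3, tolerance = 0.5)
})

test_that("steps spanning a broken central pair are excluded from the mean", {
  d <- open_bubble(ideal_spacer_19(), 10)
  seg <- detect_base_pairs(d$model, "A", "B")
  tw <- spacer_total_twist(seg)
  expect_equal(tw$n_steps_used, 16)  # 18 possible minus steps 9 and 10
  expect_equal(tw$mean_h_twist, 36, tolerance = 0.05)
})

test_that("under-twist is ideal minus measured total, with a configurable ideal", {
  d <- build_duplex(step_schedule(strrep("A", 19), twist = 36 - 82 / 19))
  seg <- detect_base_pairs(d$model, "A", "B")
  tw <- spacer_total_twist(seg)
  expect_equal(tw$under_twist, 82, tolerance = 1)
  expect_equal(under_twist(tw, ideal_twist_per_step = 34.3),
               34.3 * 19 - tw$total_twist, tolerance = 1e-9)
})

test_that("a segment without valid steps raises an insufficient-pairs error", {
  d <- open_bubble(build_duplex(step_schedule("ATG")), 2)
  seg <- detect_base_pairs(d$model, "A", "B")
  expect_error(spacer_total_twist(seg), "insufficient")
})

test_that("step tables export with W3DNA-style headers", {
  d <- build_duplex(step_schedule("ATGCA"))
  steps <- step_parameter_table(detect_base_pairs(d$model, "A", "B"))
  path <- tempfile(fileext = ".tsv")
  spacergeom::write_step_table(steps, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_true(all(c("Shift", "Roll", "h-Twist") %in% hdr))
  expect_equal(nrow(read.delim(path, check.names = FALSE)), 4)
})
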