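test_that("group centroids match direct means and handle trivial cases", {
  at <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                   x = 1, y = 2, z = 3)
  expect_equal(group_centroid(structure_model(at)), c(x = 1, y = 2, z = 3))
  at2 <- rbind(at, transform(at, x = -1, y = -2, z = -3, elety = "CB"))
  expect_equal(unname(group_centroid(structure_model(at2))), c(0, 0, 0))
  expect_error(group_centroid(at2[0, ]), "empty")
})

test_that("centroid of the first pair matches a brute-force atom-table mean", {
  d <- ideal_spacer_19()
  seg <- detect_base_pairs(d$model, "A", "B")
  # oracle: raw means over the atom table of A:1 and its partner B:19
  at <- d$model$atoms
  grp <- at[(at$chain == "A" & at$resno == 1) |
            (at$chain == "B" & at$resno == 19), ]
  oracle <- colMeans(grp[, c("x", "y", "z")])
  got <- spacergeom:::block_centroid(seg, 1, policy = "all")
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("spacer length equals the brute-force centroid distance", {
  d <- ideal_spacer_19()
  seg <- detect_base_pairs(d$model, "A", "B")
  at <- d$model$atoms
  cent <- function(ra, rb) {
    grp <- at[(at$chain == "A" & at$resno == ra) |
              (at$chain == "B" & at$resno == rb), ]
    colMeans(grp[, c("x", "y", "z")])
  }
  oracle <- sqrt(sum((cent(19, 1) - cent(1, 19))^2))
  expect_equal(spacer_length(seg), oracle, tolerance = 1e-9)
  expect_gt(oracle, 57); expect_lt(oracle, 64)  # ~ 18 steps x 3.38 A
})

test_that("terminal broken pairs make spacer_length fail loudly", {
  d <- open_bubble(ideal_spacer_19(), 19)
  seg <- detect_base_pairs(d$model, "A", "B")
  expect_error(spacer_length(seg), "[Tt]erminal")
})

test_that("a straight ideal duplex has kink 0 and a kinked one reads its truth", {
  d <- ideal_spacer_19()
  seg <- detect_base_pairs(d$model, "A", "B")
  expect_lt(kink_angle(seg), 0.5)
  # single central roll spike: measured centroid kink equals the analytic
  # centroid kink of the schedule
  sch <- impose_kink(step_schedule(strrep("A", 19)), 10, 30)
  truth <- attr(sch, "kink")
  segk <- detect_base_pairs(build_duplex(sch)$model, "A", "B")
  expect_equal(kink_angle(segk), truth$centroid_kink, tolerance = 0.2)
  expect_equal(truth$bend, 30, tolerance = 1e-6)
})

test_that("the terminal-block axis-fit oracle recovers the imposed bend", {
  for (spike in c(20, 45, 58)) {
    sch <- impose_kink(step_schedule(strrep("A", 19)), 10, spike)
    d <- build_duplex(sch)
    seg <- detect_base_pairs(d$model, "A", "B")
    origins <- t(vapply(seg$pair_frames, function(f) f$origin, numeric(3)))
    axis_of <- function(rows) prcomp(origins[rows, ])$rotation[, 1]
    a1 <- axis_of(1:6); a2 <- axis_of(14:19)
    ang <- acos(min(1, abs(sum(a1 * a2)))) * 180 / pi
    expect_equal(ang, spike, tolerance = 2)
    expect_equal(ang, attr(sch, "kink")$bend, tolerance = 2)
  }
})

test_that("two adjacent half-spikes bend like the composed rotation", {
  sch1 <- impose_kink(step_schedule(strrep("A", 19)), 9, 29)
  sch2 <- impose_kink(sch1, 10, 29)
  # oracle: compose the two roll rotations with the intervening twist
  Rz <- rotation_about(c(0, 0, 1), 36)
  Ry <- rotation_about(c(0, 1, 0), 29)
  z0 <- c(0, 0, 1)
  z1 <- Ry %*% Rz %*% Ry %*% z0
  oracle <- acos(sum(z0 * z1)) * 180 / pi
  expect_equal(attr(sch2, "kink")$bend, oracle, tolerance = 0.5)
  expect_lt(oracle, 58)  # composition partially cancels across the twist
})

test_that("kink increases and spacer length decreases with central bend", {
  kinks <- c(0, 15, 30, 45, 60)
  meas <- sapply(kinks, function(k) {
    sch <- step_schedule(strrep("A", 19))
    if (k > 0) sch <- impose_kink(sch, 10, k)
    seg <- detect_base_pairs(build_duplex(sch)$model, "A", "B")
    # frame-origin length isolates the axis geometry from the helical-phase
    # offset of atom centroids
    c(kink = kink_angle(seg), L = spacer_length(seg, atom_policy = "frame"))
  })
  expect_true(all(diff(meas["kink", ]) > 0))
  expect_true(all(diff(meas["L", ]) < 0))
})

test_that("partition handling: 6/7/6 automatic for 19 bp, explicit otherwise", {
  seg <- detect_base_pairs(ideal_spacer_19()$model, "A", "B")
  expect_equal(spacergeom:::auto_partition(19), c(6, 7, 6))
  expect_equal(spacergeom:::auto_partition(17), c(5, 7, 5))
  expect_error(spacergeom:::auto_partition(18), "partition")
  expect_error(kink_angle(seg, partition = c(5, 7, 5)), "sums to 17")
})

test_that("bubble size counts the longest bounded unpaired run", {
  d0 <- build_duplex(step_schedule(strrep("A", 30)))
  seg0 <- detect_base_pairs(d0$model, "A", "B")
  expect_equal(bubble_size(seg0)$size, 0L)

  d13 <- open_bubble(build_duplex(step_schedule(strrep("A", 30))), 10:22)
  seg13 <- detect_base_pairs(d13$model, "A", "B")
  b <- bubble_size(seg13)
  expect_equal(b$size, 13L)
  expect_equal(b$nt_size, 13L)
  expect_equal(c(b$start, b$end), c(10L, 22L))
  expect_false(b$open_ended)

  # 14-nt bubble minus 13-nt bubble reproduces a 1-nt expansion
  d14 <- open_bubble(build_duplex(step_schedule(strrep("A", 30))), 10:23)
  seg14 <- detect_base_pairs(d14$model, "A", "B")
  expect_equal(bubble_size(seg14)$size - b$size, 1L)
})

test_that("an unpaired run touching the edge warns open-ended", {
  d <- open_bubble(build_duplex(step_schedule(strrep("A", 12))), 1:4)
  seg <- detect_base_pairs(d$model, "A", "B")
  expect_warning(b <- bubble_size(seg), "open-ended")
  expect_equal(b$size, 4L)
})

test_that("spacer_report bundles all metrics and recovers the remodeling schedule", {
  d <- remodeled_spacer(kink = 58, unwind = 82)
  rep <- spacer_report(d$model, "A", "B")
  expect_equal(rep$n_pairs, 18)
  expect_equal(rep$n_unpaired, 1)
  expect_equal(rep$kink_angle, 58, tolerance = 2)
  expect_equal(rep$twist$under_twist, 82, tolerance = 1)
  expect_equal(rep$partition, c(6, 7, 6))
  expect_equal(rep$twist$n_steps_used, 16)
  expect_true(rep$spacer_length < 61)  # bent spacer is shorter than straight
  path <- tempfile(fileext = ".json")
  write_report_json(rep, path)
  vals <- jsonlite::read_json(path)
  expect_equal(vals$bubble_size, 1L)
  expect_equal(vals$under_twist, 82, tolerance = 1)
})

test_that("remodeling metrics are invariant under rigid motion and relabeling", {
  d <- remodeled_spacer()
  seg <- detect_base_pairs(d$model, "A", "B")
  L0 <- spacer_length(seg); k0 <- kink_angle(seg)
  u0 <- spacer_total_twist(seg)$under_twist
  moved <- transform_structure(d$model, random_rotation(31), random_translation(31))
  segm <- detect_base_pairs(moved, "A", "B")
  expect_equal(spacer_length(segm), L0, tolerance = 1e-6)
  expect_equal(kink_angle(segm), k0, tolerance = 1e-6)
  expect_equal(spacer_total_twist(segm)$under_twist, u0, tolerance = 1e-6)
  # 5'<->3' relabeling: analyze from the other strand
  segr <- detect_base_pairs(d$model, "B", "A")
  expect_equal(spacer_length(segr), L0, tolerance = 0.01)
  expect_equal(kink_angle(segr), k0, tolerance = 0.1)
  expect_equal(spacer_total_twist(segr)$under_twist, u0, tolerance = 0.1)
})
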