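test_that("superposing identical sets gives identity and zero rmsd", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("a noiseless rotation is recovered to 1e-4 degrees", {
  set.seed(2)
  x <- matrix(rnorm(90), 30, 3)
  R <- rotation_about(c(1, 2, -1), 25)
  y <- x %*% t(R)
  sp <- kabsch_superpose(x, y)
  expect_equal(axis_angle(sp$rotation)$angle, 25, tolerance = 1e-4)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("the Kabsch fit beats random rotations on a noisy cloud", {
  set.seed(3)
  x <- matrix(rnorm(150), 50, 3)
  y <- x %*% t(rotation_about(c(0, 1, 3), 40)) + matrix(rnorm(150, sd = 0.3), 50, 3)
  sp <- kabsch_superpose(x, y)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  rmsd_under <- function(R) sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  worst <- min(vapply(1:2000, function(i) {
    rmsd_under(random_rotation(i + 5000))
  }, numeric(1)))
  expect_lte(sp$rmsd, worst + 1e-12)
})

test_that("the fit agrees with an established reference implementation", {
  set.seed(4)
  x <- matrix(rnorm(75), 25, 3)
  y <- x %*% t(rotation_about(c(2, -1, 1), 33)) +
    matrix(rnorm(75, sd = 0.2), 25, 3)
  sp <- kabsch_superpose(x, y)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(y)), mobile = as.numeric(t(x))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - y)^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "dimension")
})

test_that("identical states give zero domain motion", {
  st <- two_state_models()
  dm <- domain_motion(st$state1, st$state1, "R", "D")
  expect_equal(dm$rotation_angle, 0, tolerance = 1e-8)
  expect_equal(dm$centroid_displacement, 0, tolerance = 1e-8)
})

test_that("a constructed 39 degree / 21 A domain motion is recovered", {
  st <- two_state_models(angle = 39, dist = 21)
  dm <- domain_motion(st$state1, st$state2, "R", "D")
  expect_equal(dm$rotation_angle, 39, tolerance = 0.1)
  expect_equal(dm$centroid_displacement, 21, tolerance = 0.1)
  # invariance under a common rigid motion of both inputs of one state
  R <- random_rotation(17); tr <- random_translation(17)
  dm2 <- domain_motion(transform_structure(st$state1, R, tr),
                       transform_structure(st$state2, random_rotation(18),
                                           random_translation(18)),
                       "R", "D")
  expect_equal(dm2$rotation_angle, 39, tolerance = 0.1)
  expect_equal(dm2$centroid_displacement, 21, tolerance = 0.1)
  # symmetry of the rotation angle
  dm3 <- domain_motion(st$state2, st$state1, "R", "D")
  expect_equal(dm3$rotation_angle, dm$rotation_angle, tolerance = 1e-6)
})

test_that("unmatched residues are dropped with a warning", {
  st <- two_state_models()
  trimmed <- st$state2
  trimmed$atoms <- trimmed$atoms[!(trimmed$atoms$chain == "D" &
                                   trimmed$atoms$resno <= 3), ]
  expect_warning(dm <- domain_motion(st$state1, trimmed, "R", "D"),
                 "unmatched")
  expect_equal(dm$rotation_angle, 39, tolerance = 0.2)
})

test_that("a lone atom's SASA matches the closed form", {
  at <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "C",
                   element = "C", x = 0, y = 0, z = 0)
  s <- sasa(structure_model(at))
  exact <- 4 * pi * (1.70 + 1.40)^2
  expect_equal(s$total, exact, tolerance = 0.005 * exact)
  # two distant atoms: exactly twice the lone-atom value
  at2 <- rbind(at, transform(at, x = 50, resno = 2))
  s2 <- sasa(structure_model(at2))
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-9)
  expect_equal(s2$per_atom[1], s2$per_atom[2])
})

test_that("two overlapping spheres match the analytic cap oracle to 1%", {
  r1 <- 1.70 + 1.4; r2 <- 1.55 + 1.4
  for (d in c(1.5, 2.5, 3.0)) {
    at <- data.frame(chain = "A", resno = 1:2, resid = "LIG",
                     elety = c("C", "N"), element = c("C", "N"),
                     x = c(0, d), y = 0, z = 0)
    s <- sasa(structure_model(at))
    exact <- two_sphere_exact(r1, r2, d)
    expect_equal(s$per_atom, exact, tolerance = 0.01 * max(exact))
  }
})

test_that("SASA converges in point count and never grows when atoms are added", {
  hx <- helix_ca(10)
  s960 <- sasa(structure_model(hx))
  s3840 <- sasa(structure_model(hx), n_points = 3840)
  expect_lt(abs(s960$total - s3840$total) / s3840$total, 0.005)
  # adding atoms can only bury surface on the original set
  hx2 <- rbind(hx, helix_ca(10, chain = "B", offset = c(4, 0, 0)))
  sboth <- sasa(structure_model(hx2))
  expect_lte(sum(sboth$per_atom[1:10]), s960$total + 1e-9)
})

test_that("unknown elements fall back to the default radius with a warning", {
  at <- data.frame(chain = "A", resno = 1, resid = "UNK", elety = "X1",
                   element = "XX", x = 0, y = 0, z = 0)
  expect_warning(s <- sasa(structure_model(at)), "unknown element")
  expect_equal(s$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 1)
})

test_that("non-contacting fragments bury zero area", {
  hx <- rbind(helix_ca(8, chain = "A"),
              helix_ca(8, chain = "B", offset = c(40, 0, 0)))
  m <- structure_model(hx)
  b <- buried_area(m, "A", "B")
  expect_equal(b$buried_total, 0, tolerance = 1e-9)
})

test_that("a two-helix contact interface matches a 10x-density recomputation", {
  hx <- rbind(helix_ca(12, chain = "A"),
              helix_ca(12, chain = "B", offset = c(6.5, 0, 0)))
  m <- structure_model(hx)
  b <- buried_area(m, "A", "B")
  expect_gt(b$buried_total, 50)  # the fixture is designed to make contact
  b10 <- buried_area(m, "A", "B", n_points = 9600)
  expect_equal(b$buried_total, b10$buried_total,
               tolerance = 0.02 * b10$buried_total)
  # symmetry in the two sides
  b_swap <- buried_area(m, "B", "A")
  expect_equal(b_swap$buried_total, b$buried_total, tolerance = 1e-9)
  expect_equal(unname(b$buried_per_side["A"] + b$buried_per_side["B"]),
               b$buried_total)
  expect_equal(b$interface_area, b$buried_total / 2)
})

test_that("overlapping interface selections are rejected", {
  hx <- helix_ca(10)
  m <- structure_model(hx)
  expect_error(buried_area(m, "A:1-6", "A:5-10"), "overlap")
})
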