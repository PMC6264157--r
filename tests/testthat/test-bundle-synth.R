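test_that("ideal helix has alpha-helical backbone dihedrals and Calpha spacing", {
  h <- ideal_helix(20, ref_params, origin = c(0, 0, 0), axis = c(0, 0, 1),
                   start_resid = 1L, chain = "A")
  dih <- hampkin:::backbone_dihedrals(h, "A")
  inner <- dih[!is.na(dih$phi) & !is.na(dih$psi), ]
  expect_true(all(inner$phi > -100 & inner$phi < -30))
  expect_true(all(inner$psi > -80 & inner$psi < -5))
  # cross-check one residue against bio3d's torsion implementation
  g <- function(r, nm) {
    a <- h$atoms
    i <- which(a$resid == r & a$atom == nm)
    c(a$x[i], a$y[i], a$z[i])
  }
  phi10 <- bio3d_dihedral(g(9, "C"), g(10, "N"), g(10, "CA"), g(10, "C"))
  expect_equal(inner$phi[inner$resid == 10], phi10, tolerance = 1e-8)

  ca <- hampkin:::coords(h)[atom_select(h, calpha = TRUE), ]
  spacing <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(spacing - 3.8) < 0.1))
  # closed-form spacing for the rise/twist/radius parameterization
  r <- ref_params$helix_radius
  tw <- ref_params$helix_twist * pi / 180
  expected <- sqrt((2 * r * sin(tw / 2))^2 + ref_params$helix_rise^2)
  expect_equal(spacing[1], expected, tolerance = 1e-10)
})

test_that("reference dimer reproduces its constructor targets exactly", {
  expect_equal(inter_monomer_distance(ref_model),
               ref_params$bundle_spacing, tolerance = 1e-9)
  da <- domain_angles(ref_model)
  expect_equal(unname(da["theta_had"]), ref_params$theta_had,
               tolerance = 1e-8)
  expect_equal(unname(da["theta_hastar_d"]), ref_params$theta_hastar_d,
               tolerance = 1e-8)
  expect_equal(unname(da["ratio"]), 116.6 / 105.5, tolerance = 1e-8)
  expect_equal(unname(average_tilt(ref_model, hamp_helix_specs())), 0,
               tolerance = 1e-8)
  expect_equal(
    marker_distance(ref_model, list(chain = "A", resid = 360),
                    list(chain = "B", resid = 248)),
    ref_params$n360_h248[1], tolerance = 1e-9)
  expect_equal(
    marker_distance(ref_model, list(chain = "B", resid = 360),
                    list(chain = "A", resid = 248)),
    ref_params$n360_h248[2], tolerance = 1e-9)
})

test_that("HAMP residue windows of the model are fully alpha-helical", {
  hc <- helix_content(ref_model)
  expect_equal(unname(hc$overall), 100)
  expect_equal(unname(hc$per_chain[["A"]]), 100)
  expect_equal(unname(hc$per_chain[["B"]]), 100)
})

test_that("gripper helices cross their companion DHp helices near the target angle", {
  ga <- gripper_dhp_angle(ref_model)
  expect_true(all(abs(ga - ref_params$gripper_angle) < 1.5))
})

test_that("zero motion schedule reproduces the reference in every frame", {
  g <- generate_trajectory(ref_params, motion_schedule(3))
  for (i in 1:3)
    expect_equal(hampkin:::coords(get_frame(g$trajectory, i)),
                 hampkin:::coords(g$reference), tolerance = 1e-12)
})

test_that("first schedule frame must be the identity motion", {
  s <- motion_schedule(2)
  s$piston_N1[1] <- 0.5
  expect_error(generate_trajectory(ref_params, s), "identity")
})

test_that("trajectory noise is reproducible under the generator seed", {
  p <- bundle_params(noise_sigma = 0.4, seed = 21)
  s <- motion_schedule(4)
  g1 <- generate_trajectory(p, s)
  g2 <- generate_trajectory(p, s)
  expect_identical(g1$trajectory$xyz, g2$trajectory$xyz)
  g3 <- generate_trajectory(bundle_params(noise_sigma = 0.4, seed = 22), s)
  expect_false(identical(g1$trajectory$xyz, g3$trajectory$xyz))
})

test_that("injected jitter has the stated per-coordinate standard deviation", {
  p <- bundle_params(noise_sigma = 0.5, seed = 8)
  g <- generate_trajectory(p, motion_schedule(200))
  dev <- sweep(matrix(g$trajectory$xyz, 200), 2,
               as.numeric(hampkin:::coords(g$reference)))
  expect_equal(sd(dev), 0.5, tolerance = 0.02)
})

test_that("overlapping residue roles in the map are rejected", {
  rm <- cpxa_residue_map()
  rm$dhp1 <- c(230L, 266L)  # collides with the HAMP C helix
  expect_error(bundle_params(residue_map = rm), "overlap")
})
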