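test_that("each injected motion is recovered exactly by its conjugate descriptor", {
  cases <- list(piston_N1 = c(-2, -0.5, 1.3, 2),
                piston_C2 = c(-1.8, 0.4, 2),
                rotation_N2 = c(-40, -12, 27, 40),
                rotation_C1 = c(-33, 8, 40),
                tilt_b = c(4, 17, 35))
  for (col in names(cases)) {
    s <- single_motion_schedule(col, cases[[col]])
    g <- generate_trajectory(ref_params, s)
    d <- hamp_descriptors(g$trajectory, g$reference, fit = FALSE)
    tcol <- if (col == "tilt_b") "tilt" else col
    expect_lt(max(abs(d[[tcol]] - s[[col]])), 1e-9)
  }
})

test_that("motions leave the non-conjugate descriptors untouched", {
  s <- single_motion_schedule("piston_N1", c(-2, 2))
  g <- generate_trajectory(ref_params, s)
  d <- hamp_descriptors(g$trajectory, g$reference, fit = FALSE)
  others <- setdiff(names(d), c("frame", "time_ps", "piston_N1",
                                "inter_monomer"))
  expect_lt(max(abs(as.matrix(d[, others]))), 1e-9)
})

test_that("helix spin about its own axis is invisible to all descriptors", {
  for (col in c("spin_N1", "spin_C2")) {
    s <- single_motion_schedule(col, c(-120, 45, 170))
    g <- generate_trajectory(ref_params, s)
    d <- hamp_descriptors(g$trajectory, g$reference, fit = FALSE)
    vals <- as.matrix(d[, setdiff(names(d), c("frame", "time_ps",
                                              "inter_monomer"))])
    expect_lt(max(abs(vals)), 1e-9)
    # the inter-monomer center distance is only approximately spin
    # invariant: the 30-residue window center lies ~0.05 A off the spin
    # axis defined by the 16-residue descriptor window
    expect_lt(max(abs(d$inter_monomer - ref_params$bundle_spacing)), 0.15)
  }
})

test_that("descriptors are invariant under rigid-body motion of the whole dimer", {
  xyz <- hampkin:::coords(ref_model)
  moved <- sweep(hampkin:::rotate_about(xyz, c(1, 2, 3), 37,
                                        origin = c(5, -4, 2)),
                 2, c(10, -7, 3), "+")
  tr <- hk_trajectory(ref_model, array(c(moved), c(1, nrow(moved), 3)))
  d <- hamp_descriptors(tr, ref_model, fit = TRUE)
  vals <- as.matrix(d[, setdiff(names(d), c("frame", "time_ps",
                                            "inter_monomer"))])
  expect_lt(max(abs(vals)), 1e-5)
  expect_equal(d$inter_monomer, ref_params$bundle_spacing,
               tolerance = 1e-9)
})

test_that("rotation sign convention matches an independent signed-angle oracle", {
  s <- single_motion_schedule("rotation_N1", c(25, -25))
  g <- generate_trajectory(ref_params, s)
  sp <- hamp_helix_specs()[["N1"]]
  ref_g <- helix_geometry(g$reference, sp)
  for (i in 2:3) {
    fr_g <- helix_geometry(get_frame(g$trajectory, i), sp)
    # oracle: signed angle via atan2 about the (shared) helix axis; the
    # descriptor counts clockwise rotation (viewed along +R) as positive
    u <- fr_g$R / sqrt(sum(fr_g$R^2))
    a <- fr_g$Rr - fr_g$Rc; a <- a - sum(a * u) * u
    b <- ref_g$Rr - ref_g$Rc; b <- b - sum(b * u) * u
    oracle <- atan2(sum(u * hampkin:::cross3(a, b)), sum(a * b)) * 180 / pi
    expect_equal(rotation(fr_g, ref_g), oracle, tolerance = 1e-8)
    expect_equal(oracle, s$rotation_N1[i], tolerance = 1e-8)
  }
})

test_that("rotation is ill-conditioned when the anchor lies on the helix axis", {
  sp <- hamp_helix_specs()[["N1"]]
  geom <- helix_geometry(ref_model, sp)
  bad <- geom
  bad$Rr <- geom$Rc + geom$R  # anchor exactly along the axis
  expect_error(rotation(bad, geom), "ill-conditioned")
})

test_that("scissor tilt equals the angle between the chain-average axes", {
  s <- single_motion_schedule("tilt_b", 20)
  g <- generate_trajectory(ref_params, s)
  fr <- get_frame(g$trajectory, 2)
  specs <- hamp_helix_specs()
  va <- hampkin:::chain_average_axis(fr, specs[c("N1", "C1")])
  vb <- hampkin:::chain_average_axis(fr, specs[c("N2", "C2")])
  oracle <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
  expect_equal(unname(average_tilt(fr, specs)), oracle, tolerance = 1e-10)
  expect_equal(oracle, 20, tolerance = 1e-9)
})

test_that("inter-monomer distance tracks a pure piston of one chain's helices", {
  s <- motion_schedule(2)
  s$piston_N2[2] <- 1.5
  s$piston_C2[2] <- -1.5  # C helix axis points -z: its center moves +z too
  g <- generate_trajectory(ref_params, s)
  fr <- get_frame(g$trajectory, 2)
  # oracle: each piston moves its 15-residue window center by delta along
  # its own reference helix axis; the chain-B center (30 residues) moves by
  # the average of the two shifts
  specs <- hamp_helix_specs("content")
  axis_of <- function(lab) {
    geom <- helix_geometry(g$reference, hamp_helix_specs()[[lab]])
    geom$R / sqrt(sum(geom$R^2))
  }
  shift <- (1.5 * axis_of("N2") - 1.5 * axis_of("C2")) / 2
  sel <- function(st, ch) atom_select(st, chain = ch,
                                      resid = c(189:203, 217:231),
                                      calpha = TRUE)
  cA <- geometric_center(g$reference, sel(g$reference, "A"))
  cB <- geometric_center(g$reference, sel(g$reference, "B"))
  oracle <- sqrt(sum((cA - cB - shift)^2))
  expect_equal(inter_monomer_distance(fr), oracle, tolerance = 1e-9)
  expect_gt(inter_monomer_distance(fr), ref_params$bundle_spacing)
})

test_that("helix content drops when a window residue is displaced off the helix", {
  m <- ref_model
  xyz <- hampkin:::coords(m)
  idx <- atom_select(m, chain = "A", resid = 195)
  xyz[idx, ] <- xyz[idx, ] + matrix(c(3, -2, 1), length(idx), 3, byrow = TRUE)
  broken <- hampkin:::set_coords(m, xyz)
  hc <- helix_content(broken)
  expect_lt(hc$per_chain[["A"]], 100)
  expect_equal(hc$per_chain[["B"]], 100)
})

test_that("descriptor tables carry frame times at the 10 ps output interval", {
  g <- generate_trajectory(ref_params, motion_schedule(4))
  d <- hamp_descriptors(g$trajectory, g$reference)
  expect_equal(d$time_ps, c(0, 10, 20, 30))
})
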