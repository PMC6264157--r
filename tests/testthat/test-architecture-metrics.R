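test_that("CA-domain swings shift the architecture angles by the scheduled amount", {
  s <- motion_schedule(3)
  s$ca_swing_a <- c(0, 6, -12)
  s$ca_swing_b <- c(0, -4, 9)
  g <- generate_trajectory(ref_params, s)
  for (i in 1:3) {
    da <- domain_angles(get_frame(g$trajectory, i))
    expect_equal(unname(da["theta_had"]),
                 ref_params$theta_had + s$ca_swing_a[i], tolerance = 1e-7)
    expect_equal(unname(da["theta_hastar_d"]),
                 ref_params$theta_hastar_d + s$ca_swing_b[i],
                 tolerance = 1e-7)
  }
})

test_that("equal vertex angles give an asymmetry ratio of one", {
  s <- motion_schedule(2)
  s$ca_swing_a[2] <- -(ref_params$theta_had - ref_params$theta_hastar_d)
  g <- generate_trajectory(ref_params, s)
  da <- domain_angles(get_frame(g$trajectory, 2))
  expect_equal(unname(da["ratio"]), 1, tolerance = 1e-7)
})

test_that("effective distance of an ambiguity group follows the r^-6 sum", {
  spec2 <- restraint_spec(
    data.frame(chain1 = c("A", "A"), resid1 = c(190L, 219L),
               chain2 = c("B", "B"), resid2 = c(190L, 219L)),
    k = 1, lower = 7, upper = 11)
  d1 <- marker_distance(ref_model, list(chain = "A", resid = 190),
                        list(chain = "B", resid = 190))
  d2 <- marker_distance(ref_model, list(chain = "A", resid = 219),
                        list(chain = "B", resid = 219))
  expect_equal(effective_distance(ref_model, spec2),
               (d1^-6 + d2^-6)^(-1 / 6), tolerance = 1e-12)
  expect_lte(effective_distance(ref_model, spec2), min(d1, d2))
  spec_min <- restraint_spec(spec2$pairs, k = 1, lower = 7, upper = 11,
                             combine = "min")
  expect_equal(effective_distance(ref_model, spec_min), min(d1, d2))
})

test_that("flat-bottom energy is zero inside the interval and half-harmonic outside", {
  tr <- scripted_distance_trajectory(c(5, 7, 9, 11, 13))
  sp <- restraint_spec(data.frame(chain1 = "A", resid1 = 1L,
                                  chain2 = "B", resid2 = 1L),
                       k = 2, lower = 7, upper = 11)
  e <- vapply(1:5, function(i) restraint_energy(get_frame(tr, i), sp),
              numeric(1))
  expect_equal(e, c(0.5 * 2 * 2^2, 0, 0, 0, 0.5 * 2 * 2^2))
})

test_that("restraint energy is continuous and smooth at the bounds", {
  sp <- restraint_spec(data.frame(chain1 = "A", resid1 = 1L,
                                  chain2 = "B", resid2 = 1L),
                       k = 3, lower = 7, upper = 11)
  e_at <- function(d) restraint_energy(get_frame(
    scripted_distance_trajectory(d), 1), sp)
  h <- 1e-6
  for (bound in c(7, 11)) {
    expect_lt(abs(e_at(bound + h) - e_at(bound - h)), 1e-8)
    # first derivative also continuous (flat-bottom is C1)
    d_in <- (e_at(bound) - e_at(bound - h)) / h
    d_out <- (e_at(bound + h) - e_at(bound)) / h
    expect_lt(abs(d_in - d_out), 1e-4)
  }
})

test_that("violation percentages match a hand count on a scripted series", {
  # 10 frames; interval [7, 11]; widened by 10% of width -> [6.6, 11.4]
  d <- c(5, 6.7, 7, 8, 9, 10, 11, 11.2, 12, 20)
  tr <- scripted_distance_trajectory(d)
  sp <- restraint_spec(data.frame(chain1 = "A", resid1 = 1L,
                                  chain2 = "B", resid2 = 1L),
                       k = 1, lower = 7, upper = 11)
  vs <- violation_stats(tr, sp)
  expect_equal(vs$strict_pct, 50)   # 5, 6.7, 11.2, 12, 20
  expect_equal(vs$widened_pct, 30)  # 5, 12, 20
  vb <- violation_stats(tr, sp, widen = "bounds")  # [6.3, 12.1]
  expect_equal(vb$widened_pct, 20)  # 5, 20
})

test_that("preset restraint tables mirror the published sets", {
  dbl <- cpxa_restraints("dbl")
  expect_length(dbl, 2L)
  expect_equal(nrow(dbl[[1]]$pairs), 2L)
  expect_equal(c(dbl[[1]]$lower, dbl[[1]]$upper), c(7, 11))
  expect_equal(c(dbl[[2]]$lower, dbl[[2]]$upper), c(13, 17))
  mid <- cpxa_restraints("mid")
  expect_length(mid, 4L)
  expect_true(all(vapply(mid, function(s) nrow(s$pairs), integer(1)) == 1L))
  tet <- cpxa_restraints("tet")
  expect_length(tet, 8L)
  expect_true(all(vapply(tet, function(s) s$k, numeric(1)) == 1))
})

test_that("restraint TSV reader joins continuation rows into ambiguity groups", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("resid1\tresid2\tforce_constant\tlower\tupper",
               "A-190\tB-190\t1\t7\t11",
               "A-219\tB-219\t\t\t",
               "A-204\tB-204\t1\t13\t17"), f)
  specs <- read_restraints(f)
  expect_length(specs, 2L)
  expect_equal(nrow(specs[[1]]$pairs), 2L)
  expect_equal(specs[[1]]$pairs$resid1, c(190L, 219L))
  expect_equal(nrow(specs[[2]]$pairs), 1L)
  expect_equal(specs[[2]]$upper, 17)
})

test_that("dissociation intervals honor threshold, duration and the isolated-event rule", {
  vals <- c(rep(2, 40), 4, 4, 4, rep(2, 40), 5, rep(2, 16))
  tr <- scripted_distance_trajectory(vals)
  sel_a <- 1L; sel_b <- 2L
  cs <- contact_series(tr, sel_a, sel_b, mode = "min")
  out <- dissociation_intervals(cs, threshold = 3, min_duration = 2L)
  expect_equal(nrow(out$intervals), 1L)
  expect_equal(out$intervals$start_frame, 41L)
  expect_equal(out$intervals$end_frame, 43L)
  expect_false(out$isolated_events)
  # raising the duration bar leaves only sub-threshold blips: isolated
  out2 <- dissociation_intervals(cs, threshold = 3, min_duration = 5L)
  expect_equal(nrow(out2$intervals), 0L)
  expect_true(out2$isolated_events)
})

test_that("contact series mean and min modes bracket each other", {
  g <- generate_trajectory(ref_params, motion_schedule(3))
  sa <- atom_select(ref_model, chain = "A", resid = 189:195, calpha = TRUE)
  sb <- atom_select(ref_model, chain = "B", resid = 189:195, calpha = TRUE)
  cmin <- contact_series(g$trajectory, sa, sb, mode = "min")
  cmean <- contact_series(g$trajectory, sa, sb, mode = "mean")
  expect_true(all(cmin$value <= cmean$value))
  expect_true(all(cmin$value > 0))
})
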