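# Synthetic CpxA-like dimer generator.
#
# Builds an idealized two-chain model of the histidine-kinase cytoplasmic
# region -- a parallel four-helix HAMP bundle, a four-helix DHp bundle, and
# two catalytic (CA) pseudo-domains with gripper helices and marker residues
# -- using 4BIV residue numbering, and animates it with exactly known piston
# / rotation / scissor-tilt / domain-swing motions. Every downstream
# descriptor can therefore be validated against ground truth without any
# structure download.

# Cylindrical offsets of backbone atoms relative to the Calpha helix, taken
# from a canonical alpha helix (phi = -57, psi = -47, ideal bond geometry):
# radius offset (A), phase offset (deg), axial offset (A).
BACKBONE_OFFSETS <- list(
  N  = c(dr = -0.724, dphase = -26.82, dz = -0.918),
  CA = c(dr = 0.000, dphase = 0.00, dz = 0.000),
  C  = c(dr = -0.609, dphase = 26.79, dz = 1.069),
  O  = c(dr = -0.355, dphase = 20.39, dz = 2.256)
)

#' Default CpxA-like residue map (4BIV numbering)
#'
#' Maps domain roles to residue ranges. The HAMP helices carry one extra
#' residue at each helix end beyond the analysis presets so that backbone
#' dihedrals are defined on every analyzed residue; DHp, gripper and CA
#' ranges follow the crystallographic definitions.
#'
#' @return Named list of `c(first, last)` residue ranges plus marker residues.
#' @export
cpxa_residue_map <- function() {
  list(hamp_n = c(188L, 204L), hamp_c = c(216L, 234L),
       dhp1 = c(235L, 266L), dhp2 = c(272L, 299L),
       ca = c(306L, 452L), gripper = c(420L, 430L),
       markers = c(N360 = 360L, R363 = 363L, D386 = 386L, H248 = 248L))
}

#' Parameters of the synthetic bundle builder
#'
#' @param helix_rise axial rise per residue (A); canonical alpha helix 1.5.
#' @param helix_twist rotation per residue (deg); canonical 100.
#' @param helix_radius Calpha helix radius (A); canonical 2.3.
#' @param bundle_spacing center-to-center distance of the two monomers in the
#'   HAMP bundle (A); this is, by construction, the inter-monomer distance
#'   reported by [inter_monomer_distance()]. Default 8.4 A, the value of the
#'   crystallographic start.
#' @param theta_had,theta_hastar_d target architecture angles (deg) at the
#'   CA- (chain A) and CA* (chain B) vertices; defaults are the
#'   crystallographic values 116.6 and 105.5.
#' @param gripper_angle target crossing angle (deg) between each gripper
#'   helix axis and its DHp helix; default 40, the autokinase regime.
#' @param n360_h248 target Calpha distances (A) `c(ca_minus, ca_star)` from
#'   N360 of one chain to H248 of the other; defaults 25 and 13.
#' @param noise_sigma sd (A) of i.i.d. Gaussian noise added per coordinate
#'   after motions.
#' @param seed integer RNG seed (fixed seed implies byte-identical output).
#' @param residue_map see [cpxa_residue_map()].
#' @return List of class `bundle_params`.
#' @export
bundle_params <- function(helix_rise = 1.5, helix_twist = 100,
                          helix_radius = 2.3, bundle_spacing = 8.4,
                          theta_had = 116.6, theta_hastar_d = 105.5,
                          gripper_angle = 40, n360_h248 = c(25, 13),
                          noise_sigma = 0, seed = 1,
                          residue_map = cpxa_residue_map()) {
  stopifnot(helix_rise > 0, helix_radius > 0, bundle_spacing > 0,
            noise_sigma >= 0, length(n360_h248) == 2)
  ranges <- residue_map[c("hamp_n", "hamp_c", "dhp1", "dhp2", "ca")]
  all_res <- unlist(lapply(ranges, function(r) seq(r[1], r[2])))
  if (anyDuplicated(all_res))
    stop("residue ranges in residue_map overlap within a chain")
  structure(list(helix_rise = helix_rise, helix_twist = helix_twist,
                 helix_radius = helix_radius, bundle_spacing = bundle_spacing,
                 theta_had = theta_had, theta_hastar_d = theta_hastar_d,
                 gripper_angle = gripper_angle, n360_h248 = n360_h248,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 residue_map = residue_map),
            class = "bundle_params")
}

#' Build an ideal alpha helix
#'
#' Generates Calpha plus backbone N, C, O atoms on coaxial helices; the
#' Calpha atoms lie exactly on a helix of the stated radius, rise and twist
#' about `axis`, and at the canonical parameters the backbone dihedrals fall
#' in the alpha-helical window used by [helix_content()].
#'
#' @param n_res number of residues (>= 5).
#' @param params a [bundle_params()] (rise/twist/radius are used).
#' @param origin point on the helix axis at the level of the first Calpha.
#' @param axis helix axis direction (need not be normalized).
#' @param start_resid residue number of the first residue.
#' @param chain chain id.
#' @param phase azimuthal phase (deg) of the first Calpha.
#' @param resname residue name for all residues.
#' @return An `hk_structure` with 4 atoms per residue.
#' @export
ideal_helix <- function(n_res, params = bundle_params(), origin = c(0, 0, 0),
                        axis = c(0, 0, 1), start_resid = 1L, chain = "A",
                        phase = 0, resname = "ALA") {
  stopifnot(n_res >= 5)
  w <- unit_vector(axis, "helix axis")
  e1 <- perp_vector(w)
  e2 <- cross3(w, e1)
  atoms <- vector("list", n_res * 4L)
  i <- 0L
  for (k in seq_len(n_res) - 1L) {
    for (nm in names(BACKBONE_OFFSETS)) {
      off <- BACKBONE_OFFSETS[[nm]]
      r <- params$helix_radius + off[["dr"]]
      ang <- (phase + k * params$helix_twist + off[["dphase"]]) * pi / 180
      p <- origin + r * (cos(ang) * e1 + sin(ang) * e2) +
        (k * params$helix_rise + off[["dz"]]) * w
      i <- i + 1L
      atoms[[i]] <- data.frame(chain = chain,
                               resid = start_resid + k,
                               resname = resname, atom = nm,
                               element = substr(nm, 1, 1),
                               x = p[1], y = p[2], z = p[3],
                               stringsAsFactors = FALSE)
    }
  }
  hk_structure(do.call(rbind, atoms))
}

# deterministic cloud of n points on a sphere (golden spiral)
sphere_cloud <- function(n, radius) {
  k <- seq_len(n)
  zu <- (2 * k - 1) / n - 1
  th <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - zu^2))
  cbind(radius * r * cos(th), radius * r * sin(th), radius * zu)
}

# centers used for the architecture-angle solve: Calpha geometric centers of
# the HAMP and DHp helix ranges over both chains
hamp_dhp_centers <- function(structure) {
  h <- geometric_center(structure,
                        atom_select(structure, resid = c(189:203, 217:231),
                                    calpha = TRUE))
  d <- geometric_center(structure,
                        atom_select(structure, resid = c(240:268, 271:298),
                                    calpha = TRUE))
  list(hamp = h, dhp = d)
}

# solve the radial offset rho > 0 such that the point (sign*rho, 0, z_mid)
# sees the HAMP and DHp centers under `target` degrees
solve_ca_position <- function(h, d, target, side_sign) {
  z_mid <- (h[3] + d[3]) / 2
  f <- function(rho) {
    p <- c(side_sign * rho, 0, z_mid)
    vec_angle(h - p, d - p) - target
  }
  rho <- stats::uniroot(f, c(0.05, 80), tol = 1e-11)$root
  c(side_sign * rho, 0, z_mid)
}

# assemble one CA pseudo-domain (cloud + gripper + markers) for a chain,
# with its Calpha centroid placed exactly at `p`
build_ca_unit <- function(params, chain, p, h248_other) {
  rm <- params$residue_map
  grip <- rm$gripper
  # the C-helix rotation-reference anchors (313, 317, 321, 325) must exist
  # as rigid Calpha points of this domain
  cloud_res <- sort(union(setdiff(seq(306L, 450L, by = 6L),
                                  c(seq(grip[1], grip[2]), rm$markers)),
                          c(313L, 317L, 321L, 325L)))
  cloud <- sphere_cloud(length(cloud_res) + 2L, radius = 6)
  extra_res <- c(rm$markers[["R363"]], rm$markers[["D386"]])
  res <- c(cloud_res, extra_res)
  resname <- c(rep("ALA", length(cloud_res)), "ARG", "ASP")
  cloud_df <- data.frame(chain = chain, resid = res, resname = resname,
                         atom = "CA", element = "C",
                         x = cloud[, 1], y = cloud[, 2], z = cloud[, 3],
                         stringsAsFactors = FALSE)
  # gripper helix tilted from the DHp axis (-z) by the target crossing angle
  g_axis <- as.vector(rotation_matrix(c(1, 0, 0), params$gripper_angle) %*%
                        c(0, 0, -1))
  grip_s <- ideal_helix(grip[2] - grip[1] + 1L, params, origin = c(0, 0, 0),
                        axis = g_axis, start_resid = grip[1], chain = chain,
                        resname = "GLY")
  unit <- rbind(cloud_df, grip_s$atoms)
  ca_idx <- which(unit$atom == "CA")
  centroid <- colMeans(as.matrix(unit[ca_idx, c("x", "y", "z")]))
  unit[, c("x", "y", "z")] <-
    sweep(as.matrix(unit[, c("x", "y", "z")]), 2, centroid - p, "-")
  # N360 placed at the target distance from H248 of the other chain, with a
  # counterweight pseudo-residue mirrored through p so the Calpha centroid
  # (hence the architecture-angle vertex) stays exactly at p
  target_d <- if (chain == "A") params$n360_h248[1] else params$n360_h248[2]
  q <- h248_other + target_d * unit_vector(p - h248_other)
  mark <- data.frame(chain = chain,
                     resid = c(rm$markers[["N360"]], 451L),
                     resname = c("ASN", "ALA"), atom = "CA", element = "C",
                     x = c(q[1], 2 * p[1] - q[1]),
                     y = c(q[2], 2 * p[2] - q[2]),
                     z = c(q[3], 2 * p[3] - q[3]),
                     stringsAsFactors = FALSE)
  rbind(unit, mark)
}

#' Build the synthetic CpxA-like dimer
#'
#' Two chains, each with an antiparallel HAMP helix pair in a parallel
#' four-helix square bundle, two DHp helices, and a CA pseudo-domain (rigid
#' point cloud plus gripper helix and marker residues). The HAMP
#' inter-monomer distance equals `bundle_spacing` exactly, and the
#' architecture angles at the CA vertices equal the constructor targets.
#'
#' @param params a [bundle_params()].
#' @return An `hk_structure`.
#' @export
build_dimer_model <- function(params = bundle_params()) {
  rm <- params$residue_map
  for (role in c("hamp_n", "hamp_c", "dhp1", "dhp2", "ca", "gripper"))
    if (is.null(rm[[role]])) stop("residue_map is missing role: ", role)
  s <- params$bundle_spacing
  rise <- params$helix_rise
  pieces <- list()
  for (ch in c("A", "B")) {
    sg <- if (ch == "A") 1 else -1
    n_len <- rm$hamp_n[2] - rm$hamp_n[1] + 1L
    c_len <- rm$hamp_c[2] - rm$hamp_c[1] + 1L
    # HAMP: N helix up, C helix down; z offsets chosen so the analyzed
    # residue windows of the two chains share the same axial span
    pieces[[paste0(ch, "_hampN")]] <- ideal_helix(
      n_len, params, origin = c(sg * s / 2, sg * s / 2, 0),
      axis = c(0, 0, 1), start_resid = rm$hamp_n[1], chain = ch)
    pieces[[paste0(ch, "_hampC")]] <- ideal_helix(
      c_len, params, origin = c(sg * s / 2, -sg * s / 2, n_len * rise),
      axis = c(0, 0, -1), start_resid = rm$hamp_c[1], chain = ch)
    d1_len <- rm$dhp1[2] - rm$dhp1[1] + 1L
    d2_len <- rm$dhp2[2] - rm$dhp2[1] + 1L
    pieces[[paste0(ch, "_dhp1")]] <- ideal_helix(
      d1_len, params, origin = c(sg * s / 2, sg * s / 2, -2),
      axis = c(0, 0, -1), start_resid = rm$dhp1[1], chain = ch)
    pieces[[paste0(ch, "_dhp2")]] <- ideal_helix(
      d2_len, params, origin = c(sg * s / 2, -sg * s / 2,
                                 -2 - (d1_len - 1) * rise),
      axis = c(0, 0, 1), start_resid = rm$dhp2[1], chain = ch)
  }
  core <- do.call(rbind, lapply(pieces, function(p) p$atoms))
  core$resname[core$resid == rm$markers[["H248"]]] <- "HIS"
  core_s <- hk_structure(core)
  cen <- hamp_dhp_centers(core_s)
  h248 <- list()
  for (ch in c("A", "B"))
    h248[[ch]] <- geometric_center(core_s,
                                   atom_select(core_s, chain = ch,
                                               resid = rm$markers[["H248"]],
                                               atom = "CA"))
  ca_a <- build_ca_unit(params, "A",
                        solve_ca_position(cen$hamp, cen$dhp,
                                          params$theta_had, 1),
                        h248_other = h248[["B"]])
  ca_b <- build_ca_unit(params, "B",
                        solve_ca_position(cen$hamp, cen$dhp,
                                          params$theta_hastar_d, -1),
                        h248_other = h248[["A"]])
  hk_structure(rbind(core, ca_a, ca_b))
}

#' Zero motion schedule
#'
#' Per-frame ground-truth motion parameters for [generate_trajectory()]:
#' piston shifts (A, along each helix's own descriptor axis), rotation
#' angles (deg, the swing conjugate to the rotation descriptor), spin (deg,
#' rotation of a helix about its own central axis -- invisible to the
#' descriptors by construction), chain-B scissor tilt (deg), and CA-domain
#' swing deltas (deg) added to the constructor architecture-angle targets.
#' Frame 1 must remain the identity motion.
#'
#' @param n_frames number of frames (>= 1).
#' @return data.frame with one all-zero row per frame.
#' @export
motion_schedule <- function(n_frames) {
  stopifnot(n_frames >= 1)
  cols <- c(paste0("piston_", c("N1", "C1", "N2", "C2")),
            paste0("rotation_", c("N1", "C1", "N2", "C2")),
            paste0("spin_", c("N1", "C1", "N2", "C2")),
            "tilt_b", "ca_swing_a", "ca_swing_b")
  out <- as.data.frame(matrix(0, n_frames, length(cols)))
  names(out) <- cols
  out
}

helix_unit_ranges <- function(residue_map) {
  list(N1 = list(chain = "A", range = residue_map$hamp_n),
       C1 = list(chain = "A", range = residue_map$hamp_c),
       N2 = list(chain = "B", range = residue_map$hamp_n),
       C2 = list(chain = "B", range = residue_map$hamp_c))
}

#' Apply one motion-schedule entry to the base model
#'
#' Rigid-body transforms per helix or domain, with no internal deformation:
#' piston translates a HAMP helix along its own descriptor axis; rotation
#' swings it about the axis through its rotation-reference point parallel to
#' the helix axis (the motion conjugate to the rotation descriptor, which it
#' changes by exactly the scheduled angle); spin turns a helix about its own
#' central axis; tilt_b rotates the chain-B HAMP pair about an axis exactly
#' perpendicular to its average axis; CA swings re-solve the CA-domain
#' placement for the scheduled architecture angles.
#'
#' @param structure the base model from [build_dimer_model()].
#' @param motion one row of a [motion_schedule()] (data.frame or list).
#' @param params the [bundle_params()] used to build `structure`.
#' @return The transformed `hk_structure`.
#' @export
apply_motion <- function(structure, motion, params = bundle_params()) {
  motion <- as.list(motion)
  mval <- function(nm) if (is.null(motion[[nm]])) 0 else as.numeric(motion[[nm]])
  units <- helix_unit_ranges(params$residue_map)
  specs <- hamp_helix_specs("descriptor")
  xyz <- coords(structure)
  moved <- FALSE
  for (lab in names(units)) {
    u <- units[[lab]]
    idx <- atom_select(structure, chain = u$chain,
                       resid = seq(u$range[1], u$range[2]))
    geom <- helix_geometry(structure, specs[[lab]])
    axis <- geom$R / vnorm(geom$R)
    pis <- mval(paste0("piston_", lab))
    if (pis != 0) {
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, pis * axis, "+")
      moved <- TRUE
    }
    rot <- mval(paste0("rotation_", lab))
    if (rot != 0) {
      # Eq-6-style rotation descriptor is positive for a clockwise swing
      # about the helix axis, hence the sign flip
      xyz[idx, ] <- rotate_about(xyz[idx, , drop = FALSE], axis, -rot,
                                 origin = geom$Rr)
      moved <- TRUE
    }
    spin <- mval(paste0("spin_", lab))
    if (spin != 0) {
      xyz[idx, ] <- rotate_about(xyz[idx, , drop = FALSE], axis, spin,
                                 origin = geom$Rc)
      moved <- TRUE
    }
  }
  tmp <- set_coords(structure, xyz)
  tilt <- mval("tilt_b")
  if (tilt != 0) {
    v_b <- chain_average_axis(tmp, specs[c("N2", "C2")])
    ax <- c(1, 0, 0) - sum(c(1, 0, 0) * v_b) * v_b / sum(v_b * v_b)
    idx_b <- atom_select(tmp, chain = "B",
                         resid = c(seq(params$residue_map$hamp_n[1],
                                       params$residue_map$hamp_n[2]),
                                   seq(params$residue_map$hamp_c[1],
                                       params$residue_map$hamp_c[2])))
    ctr <- geometric_center(tmp, idx_b)
    xyz[idx_b, ] <- rotate_about(xyz[idx_b, , drop = FALSE], ax, tilt,
                                 origin = ctr)
    tmp <- set_coords(tmp, xyz)
    moved <- TRUE
  }
  sw_a <- mval("ca_swing_a"); sw_b <- mval("ca_swing_b")
  if (sw_a != 0 || sw_b != 0) {
    cen <- hamp_dhp_centers(tmp)
    for (ch in c("A", "B")) {
      target <- if (ch == "A") params$theta_had + sw_a else
        params$theta_hastar_d + sw_b
      p_new <- solve_ca_position(cen$hamp, cen$dhp, target,
                                 if (ch == "A") 1 else -1)
      idx <- atom_select(tmp, chain = ch,
                         resid = seq(params$residue_map$ca[1],
                                     params$residue_map$ca[2]))
      ca_idx <- intersect(idx, atom_select(tmp, calpha = TRUE))
      p_old <- geometric_center(tmp, ca_idx)
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, p_new - p_old, "+")
    }
    tmp <- set_coords(tmp, xyz)
    moved <- TRUE
  }
  if (!moved) structure else tmp
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Applies the motion schedule frame by frame to the base model, adds i.i.d.
#' Gaussian positional noise (sd `noise_sigma`) after the motions, and
#' returns the trajectory together with a machine-readable ground-truth
#' record. Identical (params, schedule, seed) give identical output, byte
#' for byte when written.
#'
#' @param params a [bundle_params()].
#' @param schedule a [motion_schedule()] data.frame; frame 1 must be the
#'   identity motion.
#' @param out_dir optional directory; when given, writes `trajectory.pdb`
#'   (multi-model), `topology.pdb`, and `ground_truth.json`.
#' @return List with `trajectory` (`hk_trajectory`), `reference` (the base
#'   model), and `ground_truth` (the schedule plus the absolute architecture
#'   angles on frames where CA swings were applied).
#' @export
generate_trajectory <- function(params = bundle_params(),
                                schedule = motion_schedule(1),
                                out_dir = NULL) {
  stopifnot(nrow(schedule) >= 1)
  if (any(abs(as.numeric(schedule[1, ])) > 0))
    stop("frame 1 of the schedule must be the identity motion")
  base <- build_dimer_model(params)
  nat <- nrow(base$atoms)
  nf <- nrow(schedule)
  arr <- array(NA_real_, c(nf, nat, 3))
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  for (f in seq_len(nf)) {
    fr <- apply_motion(base, schedule[f, ], params)
    xyz <- coords(fr)
    if (params$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(nat * 3, sd = params$noise_sigma),
                          nat, 3)
    arr[f, , ] <- xyz
  }
  traj <- hk_trajectory(base, arr)
  gt <- schedule
  gt$theta_had <- ifelse(schedule$ca_swing_a != 0 | schedule$ca_swing_b != 0,
                         params$theta_had + schedule$ca_swing_a, NA_real_)
  gt$theta_hastar_d <- ifelse(schedule$ca_swing_a != 0 |
                                schedule$ca_swing_b != 0,
                              params$theta_hastar_d + schedule$ca_swing_b,
                              NA_real_)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_trajectory(traj, file.path(out_dir, "trajectory.pdb"))
    write_pdb(base, file.path(out_dir, "topology.pdb"))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(trajectory = traj, reference = base, ground_truth = gt)
}
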