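# Whole-protein architecture and enzymatic-state metrics: the HAMP-CA-DHp
# vertex angles and their asymmetry ratio, gripper/DHp helix crossing
# angles, marker Calpha distances, contact distance series with
# dissociation-interval detection, and flat-bottom distance restraints with
# violation bookkeeping.

#' Domain residue presets for the architecture angles
#'
#' Two conventions are kept verbatim: the `"s2"` set (HAMP 189-203 and
#' 217-231, DHp 240-268 and 271-298, CA 305-453) used for the architecture
#' angles, and the `"methods"` collective-variable set (HAMP 188-201 and
#' 219-234, DHp 235-266 and 272-299, CA 306-452).
#'
#' @param preset "s2" or "methods".
#' @return List with elements `hamp`, `dhp` (residues pooled over both
#'   chains) and `ca` (residues, per chain).
#' @export
domain_presets <- function(preset = c("s2", "methods")) {
  preset <- match.arg(preset)
  switch(preset,
         s2 = list(hamp = c(189:203, 217:231), dhp = c(240:268, 271:298),
                   ca = 305:453),
         methods = list(hamp = c(188:201, 219:234), dhp = c(235:266, 272:299),
                        ca = 306:452))
}

#' Architecture angles and asymmetry ratio
#'
#' The angle at each CA-domain center between the directions to the HAMP
#' center and to the DHp center (all geometric centers of Calpha). theta_HAD
#' uses the CA- domain (chain A), theta_HA*D the CA* domain (chain B); their
#' ratio indexes the asymmetry of the HAMP/DHp arrangement (about 1.1 in the
#' crystallographic start, larger in segmental-motion conformations, close
#' to 1 for symmetric arrangements).
#'
#' @param structure an `hk_structure`.
#' @param preset see [domain_presets()].
#' @param ca_minus_chain,ca_star_chain chains of the CA- and CA* domains.
#' @return Named numeric: `theta_had`, `theta_hastar_d` (deg), `ratio`.
#' @export
domain_angles <- function(structure, preset = "s2",
                          ca_minus_chain = "A", ca_star_chain = "B") {
  p <- if (is.character(preset)) domain_presets(preset) else preset
  ctr <- function(chain, resids) {
    sel <- atom_select(structure, chain = chain, resid = resids,
                       calpha = TRUE)
    if (length(sel) == 0L)
      stop("no Calpha found for domain (chain ",
           paste(chain, collapse = "/"), ")")
    geometric_center(structure, sel)
  }
  h <- ctr(c(ca_minus_chain, ca_star_chain), p$hamp)
  d <- ctr(c(ca_minus_chain, ca_star_chain), p$dhp)
  vertex_angle <- function(ca_chain) {
    c0 <- ctr(ca_chain, p$ca)
    u <- h - c0; v <- d - c0
    if (vnorm(u) < 1e-8 || vnorm(v) < 1e-8)
      stop("coincident domain centers")
    vec_angle(u, v)
  }
  t_had <- vertex_angle(ca_minus_chain)
  t_hastar <- vertex_angle(ca_star_chain)
  c(theta_had = t_had, theta_hastar_d = t_hastar, ratio = t_had / t_hastar)
}

helix_axis_4ca <- function(structure, chain, resids) {
  sel <- atom_select(structure, chain = chain, resid = resids, calpha = TRUE)
  got <- structure$atoms$resid[sel]
  miss <- setdiff(resids, got)
  if (length(miss) > 0L)
    stop("missing Calpha in chain ", chain, ": ",
         paste(utils::head(miss, 6L), collapse = ", "))
  xyz <- coords(structure)[sel[order(got)], , drop = FALSE]
  n <- nrow(xyz)
  v <- colMeans(xyz[1:4, , drop = FALSE]) -
    colMeans(xyz[(n - 3):n, , drop = FALSE])
  if (vnorm(v) < 1e-8) stop("degenerate helix axis")
  v
}

#' Gripper/DHp helix crossing angles
#'
#' Angle between the head-tail axis (four-Calpha means) of each gripper
#' helix (residues 420-430) and that of its companion DHp helix (residues
#' 235-255): the CA* gripper pairs with DHp helix 1A and the CA- gripper
#' with helix 1B. Around 40 degrees in the autokinase state.
#'
#' @param structure an `hk_structure`.
#' @param gripper,dhp_helix residue windows of the two helices.
#' @param ca_minus_chain,ca_star_chain chains carrying CA- and CA*.
#' @return Named numeric (deg, in [0, 180]): `ca_minus`, `ca_star`.
#' @export
gripper_dhp_angle <- function(structure, gripper = 420:430,
                              dhp_helix = 235:255,
                              ca_minus_chain = "A", ca_star_chain = "B") {
  g_minus <- helix_axis_4ca(structure, ca_minus_chain, gripper)
  g_star <- helix_axis_4ca(structure, ca_star_chain, gripper)
  h1a <- helix_axis_4ca(structure, ca_minus_chain, dhp_helix)
  h1b <- helix_axis_4ca(structure, ca_star_chain, dhp_helix)
  c(ca_minus = vec_angle(g_minus, h1b), ca_star = vec_angle(g_star, h1a))
}

#' Distance between two labeled atoms
#'
#' @param structure an `hk_structure`.
#' @param a,b lists `list(chain=, resid=, atom=)` (atom defaults to "CA").
#' @return Euclidean distance (A).
#' @export
marker_distance <- function(structure, a, b) {
  get1 <- function(spec) {
    if (is.null(spec$atom)) spec$atom <- "CA"
    sel <- atom_select(structure, chain = spec$chain, resid = spec$resid,
                       atom = spec$atom)
    if (length(sel) != 1L)
      stop("atom ", spec$chain, "-", spec$resid, "-", spec$atom,
           " not found (or not unique)")
    coords(structure)[sel, ]
  }
  vnorm(get1(a) - get1(b))
}

#' Per-frame contact distance between two atom groups
#'
#' For each frame, the mean (or minimum) over all cross-pair distances
#' between the two groups.
#'
#' @param traj an `hk_trajectory`.
#' @param sel_a,sel_b integer atom selections on the topology (non-empty).
#' @param mode "mean" or "min".
#' @return A [descriptor_series()] (A).
#' @export
contact_series <- function(traj, sel_a, sel_b, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("empty atom group in contact_series()")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- traj$xyz[i, , ]
    d <- outer(seq_along(sel_a), seq_along(sel_b),
               Vectorize(function(p, q) vnorm(xyz[sel_a[p], ] -
                                                xyz[sel_b[q], ])))
    if (mode == "mean") mean(d) else min(d)
  }, numeric(1))
  descriptor_series(vals, times = traj$times,
                    name = paste0("contact_", mode), units = "A")
}

#' Detect dissociation intervals in a distance series
#'
#' Maximal runs of frames with distance above the threshold (default 3 A,
#' the hydrogen-bond dissociation rule); runs shorter than `min_duration`
#' frames are dropped. When the total above-threshold fraction is below 5%
#' and no run reaches `min_duration`, the series is flagged as showing only
#' a few isolated dissociation events.
#'
#' @param series a [descriptor_series()] or numeric vector.
#' @param threshold dissociation threshold (A).
#' @param min_duration minimum run length in frames.
#' @return List with `intervals` (data.frame start/end frames and times),
#'   `final_value`, and `isolated_events` flag.
#' @export
dissociation_intervals <- function(series, threshold = 3.0,
                                   min_duration = 1L) {
  if (is.data.frame(series)) {
    vals <- series$value; times <- series$time_ps
  } else {
    vals <- as.numeric(series); times <- (seq_along(vals) - 1) * 10
  }
  if (length(vals) == 0L) stop("empty series")
  above <- vals > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  intervals <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                          start_time = times[starts[keep]],
                          end_time = times[ends[keep]])
  isolated <- mean(above) < 0.05 && !any(keep) && any(above)
  list(intervals = intervals, final_value = vals[length(vals)],
       isolated_events = isolated)
}

# ---- flat-bottom distance restraints ------------------------------------

#' Flat-bottom distance restraint specification
#'
#' A harmonic restraint on a Calpha-Calpha distance that is zero inside
#' [lower, upper] and half-harmonic outside. Several pairs form an ambiguity
#' group combined into one effective distance.
#'
#' @param pairs data.frame with columns `chain1`, `resid1`, `chain2`,
#'   `resid2` (one row per pair; more than one row makes the restraint
#'   ambiguous).
#' @param k force constant, kcal/(mol A^2). The printed unit of the
#'   restraint tables is "kcal/mol"; dimensional consistency of a harmonic
#'   distance restraint requires kcal/(mol A^2), which is how it is read.
#' @param lower,upper bounds (A), lower < upper.
#' @param combine ambiguity combination: `"r6"` (effective distance
#'   `(sum d^-6)^(-1/6)`, the standard ambiguous-restraint treatment) or
#'   `"min"`.
#' @param atom restrained atom name (default "CA").
#' @return List of class `restraint_spec`.
#' @export
restraint_spec <- function(pairs, k = 1, lower, upper,
                           combine = c("r6", "min"), atom = "CA") {
  combine <- match.arg(combine)
  stopifnot(nrow(pairs) >= 1L, lower < upper, k > 0)
  structure(list(pairs = pairs, k = k, lower = lower, upper = upper,
                 combine = combine, atom = atom),
            class = "restraint_spec")
}

restraint_pair_distances <- function(structure, spec) {
  vapply(seq_len(nrow(spec$pairs)), function(i) {
    p <- spec$pairs[i, ]
    marker_distance(structure,
                    list(chain = p$chain1, resid = p$resid1, atom = spec$atom),
                    list(chain = p$chain2, resid = p$resid2, atom = spec$atom))
  }, numeric(1))
}

#' Effective distance of a restraint
#'
#' Single-pair restraints return the plain distance; ambiguity groups are
#' combined as `(sum_k d_k^-6)^(-1/6)` (always <= the minimum pair distance)
#' or as the minimum, per the spec's `combine` mode.
#'
#' @param structure an `hk_structure`.
#' @param spec a [restraint_spec()].
#' @return Numeric scalar (A).
#' @export
effective_distance <- function(structure, spec) {
  d <- restraint_pair_distances(structure, spec)
  if (length(d) == 1L) return(d)
  if (spec$combine == "min") min(d) else sum(d^-6)^(-1 / 6)
}

#' Flat-bottom restraint energy
#'
#' Zero inside [lower, upper]; `0.5 k (d_eff - bound)^2` outside the nearest
#' bound. Continuous and once-differentiable at both bounds.
#'
#' @inheritParams effective_distance
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(structure, spec) {
  d <- effective_distance(structure, spec)
  if (d < spec$lower) 0.5 * spec$k * (d - spec$lower)^2
  else if (d > spec$upper) 0.5 * spec$k * (d - spec$upper)^2
  else 0
}

#' Restraint violation statistics along a trajectory
#'
#' Percentage of frames in which the effective distance falls outside the
#' restraint interval (strict) and outside the interval widened by 10%
#' (default reading: each side extended by 10% of the interval width;
#' `widen = "bounds"` instead scales each bound by 10% of its value). An
#' ambiguity group counts once per frame.
#'
#' @param traj an `hk_trajectory`.
#' @param spec a [restraint_spec()] or a list of them.
#' @param widen widening convention, `"width"` or `"bounds"`.
#' @return data.frame with one row per restraint: `strict_pct`,
#'   `widened_pct`.
#' @export
violation_stats <- function(traj, spec, widen = c("width", "bounds")) {
  widen <- match.arg(widen)
  specs <- if (inherits(spec, "restraint_spec")) list(spec) else spec
  rows <- lapply(seq_along(specs), function(si) {
    sp <- specs[[si]]
    d <- vapply(seq_len(n_frames(traj)), function(i)
      effective_distance(get_frame(traj, i), sp), numeric(1))
    if (widen == "width") {
      w <- 0.1 * (sp$upper - sp$lower)
      lo <- sp$lower - w; hi <- sp$upper + w
    } else {
      lo <- sp$lower * 0.9; hi <- sp$upper * 1.1
    }
    data.frame(restraint = si,
               strict_pct = 100 * mean(d < sp$lower | d > sp$upper),
               widened_pct = 100 * mean(d < lo | d > hi))
  })
  do.call(rbind, rows)
}

#' Preset HAMP inter-monomer restraints
#'
#' The three restraint sets used to prevent HAMP dimer dissociation during
#' enhanced-sampling runs: `"dbl"` (two ambiguous inter-chain groups at the
#' top and bottom of HAMP), `"mid"` (four unambiguous restraints at the
#' middle of HAMP), `"tet"` (eight unambiguous intra- and inter-chain
#' restraints at top and bottom). Force constants 1 kcal/(mol A^2).
#'
#' @param set "dbl", "mid" or "tet".
#' @return List of [restraint_spec()] objects.
#' @export
cpxa_restraints <- function(set = c("dbl", "mid", "tet")) {
  set <- match.arg(set)
  pr <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(chain1 = m[, 1], resid1 = as.integer(m[, 2]),
               chain2 = m[, 3], resid2 = as.integer(m[, 4]),
               stringsAsFactors = FALSE)
  }
  switch(set,
         dbl = list(
           restraint_spec(pr("A", 190, "B", 190, "A", 219, "B", 219),
                          k = 1, lower = 7, upper = 11),
           restraint_spec(pr("A", 204, "B", 204, "A", 230, "B", 230),
                          k = 1, lower = 13, upper = 17)),
         mid = list(
           restraint_spec(pr("A", 221, "A", 194), k = 1, lower = 10.3,
                          upper = 14.3),
           restraint_spec(pr("A", 221, "B", 194), k = 1, lower = 2.2,
                          upper = 6.2),
           restraint_spec(pr("B", 194, "B", 221), k = 1, lower = 10.3,
                          upper = 14.3),
           restraint_spec(pr("A", 194, "B", 221), k = 1, lower = 2.2,
                          upper = 6.2)),
         tet = list(
           restraint_spec(pr("A", 190, "A", 219), k = 1, lower = 10, upper = 14),
           restraint_spec(pr("B", 190, "B", 219), k = 1, lower = 10, upper = 14),
           restraint_spec(pr("A", 190, "B", 219), k = 1, lower = 7, upper = 11),
           restraint_spec(pr("A", 219, "B", 190), k = 1, lower = 7, upper = 11),
           restraint_spec(pr("A", 204, "A", 230), k = 1, lower = 9, upper = 13),
           restraint_spec(pr("B", 204, "B", 230), k = 1, lower = 9, upper = 13),
           restraint_spec(pr("A", 204, "B", 230), k = 1, lower = 13, upper = 17),
           restraint_spec(pr("B", 204, "A", 230), k = 1, lower = 13, upper = 17)))
}

#' Read restraints from a TSV table
#'
#' Columns: `resid1`, `resid2` (format `A-190`), `force_constant`, `lower`,
#' `upper`. A row whose bound fields are empty continues the ambiguity group
#' of the previous row, mirroring the layout of the published restraint
#' table.
#'
#' @param path TSV file path.
#' @return List of [restraint_spec()] objects.
#' @export
read_restraints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("resid1", "resid2", "force_constant", "lower", "upper")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("restraint table is missing column(s): ",
         paste(miss, collapse = ", "))
  parse_cr <- function(s) {
    parts <- strsplit(trimws(s), "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad chain-resid field: ", s)
    list(chain = parts[1], resid = as.integer(parts[2]))
  }
  specs <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    a <- parse_cr(df$resid1[i]); b <- parse_cr(df$resid2[i])
    row <- data.frame(chain1 = a$chain, resid1 = a$resid,
                      chain2 = b$chain, resid2 = b$resid,
                      stringsAsFactors = FALSE)
    blank <- trimws(df$lower[i]) == "" || is.na(df$lower[i])
    if (blank) {
      if (is.null(cur)) stop("continuation row ", i, " without a lead row")
      cur$pairs <- rbind(cur$pairs, row)
    } else {
      if (!is.null(cur)) specs[[length(specs) + 1L]] <- do.call(
        restraint_spec, cur)
      cur <- list(pairs = row, k = as.numeric(df$force_constant[i]),
                  lower = as.numeric(df$lower[i]),
                  upper = as.numeric(df$upper[i]))
    }
  }
  if (!is.null(cur)) specs[[length(specs) + 1L]] <- do.call(restraint_spec, cur)
  specs
}
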