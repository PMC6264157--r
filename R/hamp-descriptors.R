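# Kinematic descriptors of the HAMP four-helix bundle: per-helix piston
# displacement and rotation angle relative to a reference conformation, the
# inter-chain scissor (tilt) angle, the inter-monomer distance, and the
# alpha-helix content of the HAMP residue windows.

#' Helix specification for the HAMP descriptors
#'
#' @param label one of "N1", "C1" (chain A) or "N2", "C2" (chain B).
#' @param chain chain id; must agree with the label convention.
#' @param resids residue numbers of the helix window (>= 8, so that head and
#'   tail have four Calpha each).
#' @param ref_resids residue numbers of the rotation reference point
#'   (anchors in the DHp/CA region).
#' @param ref_chain chain of the reference residues (defaults to `chain`).
#' @return List of class `helix_spec`.
#' @export
helix_spec <- function(label, chain, resids, ref_resids,
                       ref_chain = chain) {
  stopifnot(label %in% c("N1", "C1", "N2", "C2"))
  expected <- if (label %in% c("N1", "C1")) "A" else "B"
  if (chain != expected)
    stop("label ", label, " maps to chain ", expected, ", got ", chain)
  if (length(resids) < 8L)
    stop("helix window needs >= 8 residues (4 Calpha per extremity)")
  structure(list(label = label, chain = chain, resids = as.integer(resids),
                 ref_resids = as.integer(ref_resids),
                 ref_chain = ref_chain),
            class = "helix_spec")
}

#' Preset HAMP helix definitions
#'
#' Three residue conventions are in use for the HAMP helices and are kept
#' verbatim, without unification: the collective-variable set (188-201 /
#' 219-234), the kinematic-descriptor set (189-204 / 217-232) and the
#' distance/helix-content set (189-203 / 217-231). Rotation reference
#' residues are 283/287/291/295 for the N helices and 313/317/321/325 for
#' the C helices.
#'
#' @param preset one of "descriptor", "cv", "content".
#' @return Named list of four [helix_spec()] objects (N1, C1, N2, C2).
#' @export
hamp_helix_specs <- function(preset = c("descriptor", "cv", "content")) {
  preset <- match.arg(preset)
  r <- switch(preset,
              descriptor = list(n = 189:204, c = 217:232),
              cv = list(n = 188:201, c = 219:234),
              content = list(n = 189:203, c = 217:231))
  ref_n <- c(283L, 287L, 291L, 295L)
  ref_c <- c(313L, 317L, 321L, 325L)
  list(N1 = helix_spec("N1", "A", r$n, ref_n),
       C1 = helix_spec("C1", "A", r$c, ref_c),
       N2 = helix_spec("N2", "B", r$n, ref_n),
       C2 = helix_spec("C2", "B", r$c, ref_c))
}

#' Geometric frame of one HAMP helix
#'
#' Head point `Rh` (mean of the four N-terminal Calpha of the window), tail
#' point `Rt` (mean of the four C-terminal Calpha), axis `R = Rh - Rt`,
#' center `Rc = (Rh + Rt)/2`, and rotation reference point `Rr` (mean of the
#' reference-residue Calpha).
#'
#' @param structure an `hk_structure`.
#' @param spec a [helix_spec()].
#' @return List of class `helix_geometry`.
#' @export
helix_geometry <- function(structure, spec) {
  sel <- atom_select(structure, chain = spec$chain, resid = spec$resids,
                     calpha = TRUE)
  got <- structure$atoms$resid[sel]
  miss <- setdiff(spec$resids, got)
  if (length(miss) > 0L)
    stop("missing Calpha for helix ", spec$label, ", residues: ",
         paste(miss, collapse = ", "))
  xyz <- coords(structure)[sel[order(got)], , drop = FALSE]
  n <- nrow(xyz)
  Rh <- colMeans(xyz[1:4, , drop = FALSE])
  Rt <- colMeans(xyz[(n - 3):n, , drop = FALSE])
  R <- Rh - Rt
  if (vnorm(R) < 1) stop("degenerate helix axis (|R| < 1 A) for ", spec$label)
  rsel <- atom_select(structure, chain = spec$ref_chain,
                      resid = spec$ref_resids, calpha = TRUE)
  rmiss <- setdiff(spec$ref_resids, structure$atoms$resid[rsel])
  if (length(rmiss) > 0L)
    stop("missing Calpha for rotation reference of ", spec$label,
         ", residues: ", paste(rmiss, collapse = ", "))
  Rr <- geometric_center(structure, rsel)
  structure(list(label = spec$label, Rh = Rh, Rt = Rt, R = R,
                 Rc = (Rh + Rt) / 2, Rr = Rr),
            class = "helix_geometry")
}

#' Piston displacement of a helix
#'
#' Signed projection of the center displacement onto the current helix axis:
#' `(Rc - Rc0) . R / |R|`, in Angstrom. Positive values move the center
#' toward the helix head.
#'
#' @param geom,ref_geom [helix_geometry()] of the analyzed frame (after
#'   [superpose_hamp()]) and of the reference conformation.
#' @return Numeric scalar (A).
#' @export
piston <- function(geom, ref_geom) {
  sum((geom$Rc - ref_geom$Rc) * geom$R) / vnorm(geom$R)
}

#' Rotation angle of a helix
#'
#' Signed angle, about the current helix axis, between the frame and
#' reference center-to-anchor vectors `Rrc = Rr - Rc` and `R0c = Rr0 - Rc0`,
#' with the axial components removed by the cross-product construction:
#' `sign(Rrc . (R0c x R)) * acos( (Rrc x R).(R0c x R) / |Rrc x R||R0c x R| )`.
#' Both vectors are taken against their own frame (the descriptor is 0 when
#' frame = reference). Range (-180, 180], degrees.
#'
#' @inheritParams piston
#' @return Numeric scalar (degrees).
#' @export
rotation <- function(geom, ref_geom) {
  u <- geom$R
  a <- geom$Rr - geom$Rc
  b <- ref_geom$Rr - ref_geom$Rc
  ax <- cross3(a, u); bx <- cross3(b, u)
  na <- vnorm(ax); nb <- vnorm(bx)
  if (na < 1e-6 * vnorm(a) * vnorm(u) || nb < 1e-6 * vnorm(b) * vnorm(u))
    stop("rotation ill-conditioned: reference vector nearly parallel to ",
         "the helix axis")
  # equivalent atan2 form of the acos expression: well-conditioned at 0
  # and 180 degrees, where acos loses half the significant digits
  ang <- atan2(vnorm(cross3(ax, bx)), sum(ax * bx)) * 180 / pi
  s <- sign(sum(a * cross3(b, u)))
  if (s == 0) ang else s * ang
}

# aligned average axis of one chain's HAMP helix pair: the C-helix head/tail
# are swapped when its axis points away from the N-helix axis, so the
# antiparallel pair does not cancel
chain_average_axis <- function(structure, specs, align = TRUE,
                               return_points = FALSE) {
  g1 <- helix_geometry(structure, specs[[1]])
  g2 <- helix_geometry(structure, specs[[2]])
  h2 <- g2$Rh; t2 <- g2$Rt
  if (align && sum(g1$R * g2$R) < 0) { h2 <- g2$Rt; t2 <- g2$Rh }
  head <- (g1$Rh + h2) / 2
  tail <- (g1$Rt + t2) / 2
  v <- head - tail
  if (vnorm(v) < 1e-6) stop("degenerate average helix axis")
  if (return_points) list(head = head, tail = tail, axis = v) else v
}

#' Scissor tilt angle between the two chains
#'
#' Angle between the average helix axes of chain A and chain B, each
#' computed from the averaged head and tail positions of that chain's two
#' HAMP helices (the C helix is direction-aligned with the N helix before
#' averaging, otherwise the antiparallel pair cancels). Reported in
#' [0, 180] degrees.
#'
#' @param structure an `hk_structure` (already fitted when comparing frames).
#' @param specs the four [helix_spec()]s, as from [hamp_helix_specs()].
#' @param align flip the C-helix direction before averaging (default TRUE).
#' @return Numeric scalar (degrees).
#' @export
average_tilt <- function(structure, specs = hamp_helix_specs("descriptor"),
                         align = TRUE) {
  va <- chain_average_axis(structure, specs[c("N1", "C1")], align = align)
  vb <- chain_average_axis(structure, specs[c("N2", "C2")], align = align)
  vec_angle(va, vb)
}

#' Superpose a frame onto the reference over the HAMP Calpha
#'
#' Calpha-only fit over all four HAMP helix windows, the frame preparation
#' step for the piston/rotation/tilt descriptors.
#'
#' @param frame,reference `hk_structure` objects.
#' @param specs the four [helix_spec()]s.
#' @return The fitted frame (`hk_structure`).
#' @export
superpose_hamp <- function(frame, reference,
                           specs = hamp_helix_specs("descriptor")) {
  resids <- sort(unique(unlist(lapply(specs, `[[`, "resids"))))
  sel_f <- atom_select(frame, resid = resids, calpha = TRUE)
  sel_r <- atom_select(reference, resid = resids, calpha = TRUE)
  superpose(frame, reference, sel_f, sel_r)$fitted
}

#' Inter-monomer distance of the HAMP dimer
#'
#' Distance between the per-chain geometric centers of the Calpha atoms of
#' the HAMP helix windows (default 189-203 and 217-231), an index of dimer
#' association.
#'
#' @param structure an `hk_structure`.
#' @param resids residue numbers pooled per chain.
#' @param chains the two chain ids.
#' @return Numeric scalar (A).
#' @export
inter_monomer_distance <- function(structure,
                                   resids = c(189:203, 217:231),
                                   chains = c("A", "B")) {
  centers <- lapply(chains, function(ch) {
    sel <- atom_select(structure, chain = ch, resid = resids, calpha = TRUE)
    miss <- setdiff(resids, structure$atoms$resid[sel])
    if (length(miss) > 0L)
      stop("missing Calpha in chain ", ch, ": ",
           paste(utils::head(miss, 6L), collapse = ", "))
    geometric_center(structure, sel)
  })
  vnorm(centers[[1]] - centers[[2]])
}

# phi/psi table for one chain of a structure; rows are residues with both
# dihedrals defined (needs C of the previous and N of the next residue)
backbone_dihedrals <- function(structure, chain, resids = NULL) {
  a <- structure$atoms
  sel <- a$chain == chain & a$atom %in% c("N", "CA", "C")
  a <- a[sel, , drop = FALSE]
  if (is.null(resids)) {
    # default to residues with a complete N/CA/C backbone (markers and
    # pseudo-residues carrying only Calpha are skipped silently)
    tab <- table(a$resid)
    res <- sort(as.integer(names(tab)[tab == 3L]))
  } else res <- sort(unique(as.integer(resids)))
  getxyz <- function(r, nm) {
    i <- which(a$resid == r & a$atom == nm)
    if (length(i) != 1L) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  }
  out <- data.frame(resid = res, phi = NA_real_, psi = NA_real_)
  for (j in seq_along(res)) {
    r <- res[j]
    Cm <- getxyz(r - 1L, "C"); N <- getxyz(r, "N")
    CA <- getxyz(r, "CA"); C <- getxyz(r, "C"); Np <- getxyz(r + 1L, "N")
    if (is.null(N) || is.null(CA) || is.null(C))
      stop("missing backbone atoms for residue ", chain, "-", r)
    if (!is.null(Cm)) out$phi[j] <- dihedral(Cm, N, CA, C)
    if (!is.null(Np)) out$psi[j] <- dihedral(N, CA, C, Np)
  }
  out
}

# helical flags per residue of one chain: dihedral windows plus a minimum
# run of 3 consecutive residues; residues lacking a dihedral are non-helical
helical_flags <- function(dih) {
  ok <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= -100 & dih$phi <= -30 & dih$psi >= -80 & dih$psi <= -5
  flags <- stats::setNames(rep(FALSE, nrow(dih)), dih$resid)
  n <- nrow(dih)
  i <- 1L
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1L] && dih$resid[j + 1L] == dih$resid[j] + 1L)
        j <- j + 1L
      if (j - i + 1L >= 3L) flags[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  flags
}

#' Alpha-helix content of the HAMP residue windows
#'
#' Fraction of the analyzed residues assigned alpha-helical, averaged over
#' frames, as a percentage. Assignment uses backbone dihedral windows (phi
#' in [-100, -30], psi in [-80, -5]) with a minimum run of three consecutive
#' helical residues; residues lacking a dihedral (chain ends) count as
#' non-helical.
#'
#' @param x an `hk_structure` or `hk_trajectory`.
#' @param resids analyzed residue numbers (default 189-203 and 217-231).
#' @param chains chain ids.
#' @return List with `per_chain` (named percentages) and `overall`.
#' @export
helix_content <- function(x, resids = c(189:203, 217:231),
                          chains = c("A", "B")) {
  frames <- if (inherits(x, "hk_trajectory"))
    lapply(seq_len(n_frames(x)), function(i) get_frame(x, i)) else list(x)
  frac <- matrix(NA_real_, length(frames), length(chains),
                 dimnames = list(NULL, chains))
  for (i in seq_along(frames)) {
    for (ch in chains) {
      flags <- helical_flags(backbone_dihedrals(frames[[i]], ch))
      have <- as.character(resids)
      vals <- flags[have]
      vals[is.na(vals)] <- FALSE
      frac[i, ch] <- mean(vals)
    }
  }
  per_chain <- 100 * colMeans(frac)
  list(per_chain = per_chain, overall = mean(per_chain))
}

#' Per-frame HAMP descriptor table
#'
#' Computes, for each frame, the piston displacement and rotation angle of
#' each HAMP helix with respect to the reference conformation, the scissor
#' tilt between the chains, and the inter-monomer distance. With
#' `fit = TRUE` (the analysis convention for arbitrary trajectories) every
#' frame is first Calpha-superposed onto the reference over the four HAMP
#' helices; with `fit = FALSE` frames are assumed to already share the
#' reference frame, which is exact for synthetic trajectories generated in
#' the reference coordinate system.
#'
#' @param traj an `hk_trajectory`.
#' @param reference the reference `hk_structure` (e.g. the model the
#'   trajectory was generated from, or a crystallographic start).
#' @param specs the four [helix_spec()]s.
#' @param fit superpose each frame onto the reference first (default TRUE).
#' @param inter_monomer also report the inter-monomer distance.
#' @return data.frame with columns `frame`, `time_ps`, `piston_*` (A),
#'   `rotation_*` (deg), `tilt` (deg) and optionally `inter_monomer` (A).
#' @export
hamp_descriptors <- function(traj, reference,
                             specs = hamp_helix_specs("descriptor"),
                             fit = TRUE, inter_monomer = TRUE) {
  ref_geoms <- lapply(specs, function(sp) helix_geometry(reference, sp))
  nf <- n_frames(traj)
  labs <- names(specs)
  out <- data.frame(frame = seq_len(nf), time_ps = traj$times)
  for (l in labs) {
    out[[paste0("piston_", l)]] <- NA_real_
    out[[paste0("rotation_", l)]] <- NA_real_
  }
  out$tilt <- NA_real_
  if (inter_monomer) out$inter_monomer <- NA_real_
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    if (fit) fr <- superpose_hamp(fr, reference, specs)
    for (l in labs) {
      g <- helix_geometry(fr, specs[[l]])
      out[[paste0("piston_", l)]][i] <- piston(g, ref_geoms[[l]])
      out[[paste0("rotation_", l)]][i] <- rotation(g, ref_geoms[[l]])
    }
    out$tilt[i] <- average_tilt(fr, specs)
    if (inter_monomer) out$inter_monomer[i] <- inter_monomer_distance(fr)
  }
  attr(out, "units") <- c(piston = "A", rotation = "deg", tilt = "deg",
                          inter_monomer = "A")
  out
}
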