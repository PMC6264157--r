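#' Construct a structure object
#'
#' A structure is one frame of labeled atoms: chain id, residue number and
#' name, atom name, element, and Cartesian coordinates in Angstrom.
#' Residue numbering follows 1-based PDB conventions and is never remapped.
#'
#' @param atoms data.frame with columns `chain`, `resid`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`.
#' @param time_ps optional frame time in picoseconds.
#' @return An object of class `hk_structure`.
#' @export
hk_structure <- function(atoms, time_ps = NULL) {
  need <- c("chain", "resid", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  atoms$resid <- as.integer(atoms$resid)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, atom) records: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  structure(list(atoms = atoms, time_ps = time_ps), class = "hk_structure")
}

#' @export
print.hk_structure <- function(x, ...) {
  cat("<hk_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Select atoms of a structure
#'
#' Resolves a predicate over chain ids, residue numbers and atom names into a
#' deterministic, file-ordered integer index vector.
#'
#' @param structure an `hk_structure` (or the topology of an `hk_trajectory`).
#' @param chain character vector of chain ids, or NULL for all.
#' @param resid integer vector of residue numbers, or NULL for all.
#' @param atom character vector of atom names, or NULL for all.
#' @param backbone if TRUE, restrict to backbone heavy atoms N, CA, C, O.
#' @param calpha if TRUE, restrict to CA atoms.
#' @return Integer vector of atom indices (possibly empty).
#' @export
atom_select <- function(structure, chain = NULL, resid = NULL, atom = NULL,
                        backbone = FALSE, calpha = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% as.integer(resid)
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (backbone) keep <- keep & a$atom %in% c("N", "CA", "C", "O")
  if (calpha) keep <- keep & a$atom == "CA"
  which(keep)
}

#' Geometric center of selected atoms
#'
#' Unweighted mean position of the selected atoms. The gradient of each
#' center coordinate with respect to a member atom is 1/N (0 for
#' non-members), which is what the geometric-center collective variables of
#' the TAMD engine rely on.
#'
#' @param structure an `hk_structure`.
#' @param sel integer atom indices (e.g. from [atom_select()]); NULL = all.
#' @return Numeric length-3 vector (x, y, z).
#' @export
geometric_center <- function(structure, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(structure$atoms))
  if (length(sel) == 0L) stop("empty selection in geometric_center()")
  colMeans(coords(structure)[sel, , drop = FALSE])
}

# Kabsch least-squares rotation (proper, det = +1) mapping P onto Q.
# P, Q: n x 3 matrices of paired coordinates.
kabsch <- function(P, Q) {
  if (nrow(P) < 3L) stop("superposition needs at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  list(rotation = R, translation = t)
}

match_fit_atoms <- function(mobile, reference, sel_mobile, sel_reference) {
  km <- with(mobile$atoms[sel_mobile, ], paste(chain, resid, atom))
  kr <- with(reference$atoms[sel_reference, ], paste(chain, resid, atom))
  only_m <- setdiff(km, kr); only_r <- setdiff(kr, km)
  if (length(only_m) > 0L || length(only_r) > 0L)
    stop("fit selections do not match 1:1; unmatched atoms: ",
         paste(utils::head(c(only_m, only_r), 6L), collapse = "; "))
  list(mobile = sel_mobile[match(kr, km)], reference = sel_reference)
}

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rigid transform (rotation with det +1 plus
#' translation) fitting `mobile` onto `reference` over a fit selection.
#' Atoms are paired by (chain, resid, atom name).
#'
#' @param mobile,reference `hk_structure` objects.
#' @param sel_mobile,sel_reference integer indices of the fit atoms in each
#'   structure; defaults to all atoms.
#' @return List with `rotation` (3x3), `translation` (length 3), `fitted`
#'   (the whole mobile structure transformed) and `rmsd` (over the fit set).
#' @export
superpose <- function(mobile, reference,
                      sel_mobile = NULL, sel_reference = NULL) {
  if (is.null(sel_mobile)) sel_mobile <- seq_len(nrow(mobile$atoms))
  if (is.null(sel_reference)) sel_reference <- seq_len(nrow(reference$atoms))
  m <- match_fit_atoms(mobile, reference, sel_mobile, sel_reference)
  P <- coords(mobile)[m$mobile, , drop = FALSE]
  Q <- coords(reference)[m$reference, , drop = FALSE]
  k <- kabsch(P, Q)
  xyz <- coords(mobile) %*% t(k$rotation)
  xyz <- sweep(xyz, 2, k$translation, "+")
  fitted <- set_coords(mobile, xyz)
  d <- coords(fitted)[m$mobile, , drop = FALSE] - Q
  list(rotation = k$rotation, translation = k$translation, fitted = fitted,
       rmsd = sqrt(mean(rowSums(d^2))))
}

rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Construct a trajectory object
#'
#' Ordered frames sharing one topology. Coordinates are stored as an array
#' `[frame, atom, xyz]`. When no frame times are supplied a 10 ps spacing is
#' assumed, the stride at which coordinates are conventionally saved in the
#' production runs this package analyzes.
#'
#' @param topology an `hk_structure` describing the shared atom list.
#' @param xyz numeric array `n_frames x n_atoms x 3`.
#' @param times optional numeric vector of frame times (ps).
#' @return An object of class `hk_trajectory`.
#' @export
hk_trajectory <- function(topology, xyz, times = NULL) {
  stopifnot(inherits(topology, "hk_structure"))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != nrow(topology$atoms) ||
      dim(xyz)[3] != 3L)
    stop("xyz must be an n_frames x n_atoms x 3 array congruent with topology")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- (seq_len(dim(xyz)[1]) - 1) * 10
  if (length(times) != dim(xyz)[1])
    stop("times must have one entry per frame")
  structure(list(topology = topology, xyz = xyz, times = times),
            class = "hk_trajectory")
}

#' @export
print.hk_trajectory <- function(x, ...) {
  cat("<hk_trajectory> ", dim(x$xyz)[1], " frames, ", dim(x$xyz)[2],
      " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `hk_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Extract one frame of a trajectory as a structure
#' @param traj an `hk_trajectory`.
#' @param i frame index (1-based).
#' @return An `hk_structure`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  s <- set_coords(traj$topology, traj$xyz[i, , ])
  s$time_ps <- traj$times[i]
  s
}

# ---- PDB I/O -----------------------------------------------------------

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB line ", i, ": shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

# bio3d atom table -> hk_structure atom table, applying the insertion-code
# and alternate-location policies (reject icodes; keep highest occupancy,
# ties resolved to altloc 'A').
bio3d_to_atoms <- function(at) {
  ins <- !(is.na(at$insert) | at$insert == "" | at$insert == " ")
  if (any(ins)) {
    r <- at[which(ins)[1], ]
    stop("insertion codes are not supported (residue ", r$chain, "-",
         r$resno, r$insert, ")")
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "" & alt != " ")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt != "" & alt != " "])) {
      i <- which(key == k)
      if (length(i) > 1L) {
        best <- i[order(-occ[i], alt[i])][1]
        keep[setdiff(i, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  data.frame(chain = at$chain, resid = as.integer(at$resno),
             resname = at$resid, atom = at$elety,
             element = trimws(elem), x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Read a PDB file into a structure
#'
#' Parses ATOM/HETATM records (first MODEL if several). Residue numbers are
#' preserved exactly. Files with insertion codes are rejected; for alternate
#' locations the highest-occupancy copy is kept (ties go to altloc 'A').
#'
#' @param path path to a PDB file.
#' @return An `hk_structure`.
#' @export
read_pdb <- function(path) {
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  hk_structure(bio3d_to_atoms(pdb$atom))
}

#' Read a multi-model PDB file into a trajectory
#'
#' Each MODEL becomes one frame; all models must share the topology of the
#' first. Frame times default to a 10 ps spacing.
#'
#' @param path path to a (multi-model) PDB file.
#' @param topology optional `hk_structure` to validate against.
#' @param times optional frame times (ps).
#' @return An `hk_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, times = NULL) {
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- hk_structure(bio3d_to_atoms(pdb$atom))
  if (!is.null(topology)) {
    k1 <- with(top$atoms, paste(chain, resid, atom))
    k2 <- with(topology$atoms, paste(chain, resid, atom))
    if (!identical(k1, k2))
      stop("trajectory atoms do not match the supplied topology; first ",
           "mismatch: ", utils::head(c(setdiff(k2, k1), setdiff(k1, k2)), 1L))
  }
  nat <- nrow(top$atoms)
  xyzmat <- pdb$xyz
  if (is.null(dim(xyzmat))) xyzmat <- matrix(xyzmat, nrow = 1)
  nf <- nrow(xyzmat)
  arr <- array(NA_real_, c(nf, nat, 3))
  for (i in seq_len(nf))
    arr[i, , ] <- matrix(xyzmat[i, ], ncol = 3, byrow = TRUE)
  hk_trajectory(top, arr, times = times)
}

format_pdb_atom <- function(i, a, x, y, z) {
  name <- a$atom
  # PDB atom-name column rules: 1-3 character names start in column 14
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, name_f, substr(a$resname, 1, 3), a$chain, a$resid,
          x, y, z, 1.0, 0.0, a$element)
}

structure_pdb_lines <- function(s) {
  a <- s$atoms
  vapply(seq_len(nrow(a)), function(i)
    format_pdb_atom(i, a[i, ], a$x[i], a$y[i], a$z[i]), character(1))
}

#' Write a structure to a PDB file
#' @param structure an `hk_structure`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  writeLines(c(structure_pdb_lines(structure), "END"), path)
  invisible(path)
}

#' Write a trajectory to a multi-model PDB file
#' @param traj an `hk_trajectory`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$topology$atoms
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$xyz[f, , , drop = TRUE]
    writeLines(vapply(seq_len(nrow(a)), function(i)
      format_pdb_atom(i, a[i, ], xyz[i, 1], xyz[i, 2], xyz[i, 3]),
      character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- RMSD / RMSF -------------------------------------------------------

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is rigid-body fitted onto the reference over `fit_sel`, then
#' the RMSD is evaluated over `measure_sel` (defaults to the fit selection).
#'
#' @param traj an `hk_trajectory`.
#' @param reference an `hk_structure` sharing (chain, resid, atom) labels.
#' @param fit_sel,measure_sel integer selections on the trajectory topology
#'   (NULL = all atoms).
#' @return A [descriptor_series()] in Angstrom.
#' @export
rmsd_series <- function(traj, reference, fit_sel = NULL, measure_sel = NULL) {
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(traj$topology$atoms))
  if (is.null(measure_sel)) measure_sel <- fit_sel
  ref_sel <- match_selection(traj$topology, reference, fit_sel)
  ref_meas <- match_selection(traj$topology, reference, measure_sel)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- get_frame(traj, i)
    fit <- superpose(fr, reference, fit_sel, ref_sel)
    rmsd_xyz(coords(fit$fitted)[measure_sel, , drop = FALSE],
             coords(reference)[ref_meas, , drop = FALSE])
  }, numeric(1))
  descriptor_series(vals, times = traj$times, name = "rmsd", units = "A")
}

# map a selection on topology `from` to the matching atoms of structure `to`
match_selection <- function(from, to, sel) {
  kf <- with(from$atoms[sel, ], paste(chain, resid, atom))
  kt <- with(to$atoms, paste(chain, resid, atom))
  idx <- match(kf, kt)
  if (anyNA(idx))
    stop("selection atoms missing from reference: ",
         paste(utils::head(kf[is.na(idx)], 6L), collapse = "; "))
  idx
}

#' Root-mean-square fluctuations per atom or residue
#'
#' Every frame is superposed onto the reference over `fit_sel`; the RMSF of
#' an atom is the root-mean-square deviation from its trajectory-mean
#' position. With `group_by_residue = TRUE` values are averaged over each
#' residue's selected atoms.
#'
#' @param traj an `hk_trajectory` with at least 2 frames.
#' @param reference reference `hk_structure` for the superposition.
#' @param fit_sel integer selection used for fitting (NULL = all atoms).
#' @param measure_sel atoms to report (NULL = fit selection).
#' @param group_by_residue average per residue (default TRUE).
#' @return data.frame with columns `chain`, `resid` (and `atom` when not
#'   grouped) and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, reference, fit_sel = NULL, measure_sel = NULL,
                 group_by_residue = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(traj$topology$atoms))
  if (is.null(measure_sel)) measure_sel <- fit_sel
  ref_sel <- match_selection(traj$topology, reference, fit_sel)
  nf <- n_frames(traj)
  fitted <- array(NA_real_, c(nf, length(measure_sel), 3))
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    fit <- superpose(fr, reference, fit_sel, ref_sel)
    fitted[i, , ] <- coords(fit$fitted)[measure_sel, , drop = FALSE]
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- vapply(seq_along(measure_sel), function(j)
    mean(rowSums(sweep(fitted[, j, , drop = TRUE], 2, mean_pos[j, ])^2)),
    numeric(1))
  out <- data.frame(chain = traj$topology$atoms$chain[measure_sel],
                    resid = traj$topology$atoms$resid[measure_sel],
                    atom = traj$topology$atoms$atom[measure_sel],
                    rmsf = sqrt(dev2), stringsAsFactors = FALSE)
  if (group_by_residue) {
    agg <- stats::aggregate(rmsf ~ chain + resid, data = out, FUN = mean)
    agg[order(agg$chain, agg$resid), , drop = FALSE]
  } else out
}

# ---- descriptor series -------------------------------------------------

#' Named per-frame scalar series
#'
#' Lightweight container used by all descriptor modules: a data.frame with
#' columns `frame`, `time_ps`, `value` plus `name` and `units` attributes.
#'
#' @param values numeric per-frame values.
#' @param times frame times in ps (default 10 ps spacing).
#' @param name descriptor name.
#' @param units unit string (e.g. "A", "deg").
#' @return data.frame of class `descriptor_series`.
#' @export
descriptor_series <- function(values, times = NULL, name = "value",
                              units = "") {
  if (is.null(times)) times <- (seq_along(values) - 1) * 10
  out <- data.frame(frame = seq_along(values), time_ps = times,
                    value = as.numeric(values))
  attr(out, "name") <- name
  attr(out, "units") <- units
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' Export a descriptor series as CSV
#'
#' Writes columns `frame`, `time_ps`, `value`, `units`.
#'
#' @param series a [descriptor_series()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$units <- attr(series, "units")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
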