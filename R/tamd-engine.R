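# Temperature-accelerated molecular dynamics on pluggable systems.
#
# The physical coordinates x follow Langevin dynamics under the extended
# potential U(x, z) = V(x) + (kappa/2) ||theta(x) - z||^2 (BAOAB splitting);
# the collective-variable targets z follow overdamped dynamics at the
# artificial thermal energy beta_bar^-1 with friction gamma_bar:
#
#   dz = (dt / gamma_bar) kappa (theta(x) - z)
#        + sqrt(2 dt / (gamma_bar beta_bar)) N(0, 1).
#
# Units throughout: kcal/mol, Angstrom, ps; beta^-1 and beta_bar^-1 are
# thermal energies in kcal/mol (k_B folded in).

#' Define a system for the TAMD engine
#'
#' A system bundles the potential, its gradient, a collective-variable map
#' with Jacobian, and a diagonal mass vector. The gradient and Jacobian are
#' validated against central finite differences at a few random points
#' (relative error < 1e-4) unless `validate = FALSE`.
#'
#' @param dimension number of physical coordinates.
#' @param potential function(x) -> scalar energy (kcal/mol).
#' @param gradient function(x) -> length-`dimension` gradient.
#' @param cv function(x) -> collective variable vector theta(x).
#' @param cv_jacobian function(x) -> (n_cv x dimension) Jacobian matrix.
#' @param mass diagonal masses (scalar recycled), default 1.
#' @param n_cv number of collective variables.
#' @param validate finite-difference check of gradient and Jacobian.
#' @return A `system_model` list.
#' @export
system_model <- function(dimension, potential, gradient, cv, cv_jacobian,
                         mass = 1, n_cv = NULL, validate = TRUE) {
  stopifnot(dimension >= 1)
  mass <- rep_len(mass, dimension)
  if (any(mass <= 0)) stop("masses must be positive")
  x0 <- rep(0, dimension)
  if (is.null(n_cv)) n_cv <- length(cv(x0))
  sys <- structure(list(dimension = dimension, potential = potential,
                        gradient = gradient, cv = cv,
                        cv_jacobian = cv_jacobian, mass = mass,
                        n_cv = n_cv),
                   class = "system_model")
  if (validate) validate_system(sys)
  sys
}

# spot-check analytic derivatives against central differences
validate_system <- function(sys, n_points = 3L, h = 1e-5) {
  pts <- lapply(seq_len(n_points), function(i)
    sin(seq_len(sys$dimension) * 7.3 + i * 2.1))
  for (x in pts) {
    g <- sys$gradient(x)
    j <- sys$cv_jacobian(x)
    for (k in seq_len(sys$dimension)) {
      e <- numeric(sys$dimension); e[k] <- h
      g_fd <- (sys$potential(x + e) - sys$potential(x - e)) / (2 * h)
      scale <- max(abs(g_fd), abs(g[k]), 1)
      if (abs(g[k] - g_fd) / scale > 1e-4)
        stop("gradient/potential mismatch at coordinate ", k,
             " (analytic ", signif(g[k], 6), ", FD ", signif(g_fd, 6), ")")
      j_fd <- (sys$cv(x + e) - sys$cv(x - e)) / (2 * h)
      if (any(abs(j[, k] - j_fd) / pmax(abs(j_fd), abs(j[, k]), 1) > 1e-4))
        stop("CV Jacobian mismatch at coordinate ", k)
    }
  }
  invisible(sys)
}

#' One-dimensional harmonic well
#'
#' `V(x) = 0.5 k_w (x - x0)^2` with the identity collective variable.
#'
#' @param k_w force constant, kcal/(mol A^2).
#' @param x0 minimum position (A).
#' @return A [system_model()].
#' @export
sys_harmonic <- function(k_w = 1, x0 = 0) {
  system_model(
    dimension = 1,
    potential = function(x) 0.5 * k_w * (x[1] - x0)^2,
    gradient = function(x) k_w * (x[1] - x0),
    cv = function(x) x[1],
    cv_jacobian = function(x) matrix(1, 1, 1))
}

#' One-dimensional symmetric double well
#'
#' `V(x) = h (x^2 - 1)^2`: minima at x = -1 and +1 separated by a barrier of
#' height `h` at x = 0.
#'
#' @param h barrier height, kcal/mol.
#' @return A [system_model()].
#' @export
sys_double_well <- function(h = 6) {
  system_model(
    dimension = 1,
    potential = function(x) h * (x[1]^2 - 1)^2,
    gradient = function(x) 4 * h * x[1] * (x[1]^2 - 1),
    cv = function(x) x[1],
    cv_jacobian = function(x) matrix(1, 1, 1))
}

#' Flat potential in a smooth box
#'
#' Zero potential inside |x| < `half_width`, confining quartic walls
#' outside. Useful as a flat-free-energy control.
#'
#' @param half_width box half-width (A).
#' @param k_wall wall stiffness.
#' @return A [system_model()].
#' @export
sys_flat_box <- function(half_width = 2, k_wall = 10) {
  ex <- function(x) max(0, abs(x) - half_width) * sign(x)
  system_model(
    dimension = 1,
    potential = function(x) k_wall * ex(x[1])^4,
    gradient = function(x) 4 * k_wall * ex(x[1])^3,
    cv = function(x) x[1],
    cv_jacobian = function(x) matrix(1, 1, 1))
}

#' Geometric-center collective variable
#'
#' One CV component per Cartesian axis: the mean over a group of points. On
#' a system whose coordinates are a flattened (n_points x 3) array, group
#' `idx` (point indices) maps to theta = colMeans(x[idx, ]), with constant
#' Jacobian entries 1/length(idx).
#'
#' @param idx point (not coordinate) indices of the group.
#' @param n_points total number of points in the system.
#' @return List with `cv` and `jacobian` functions, composable into
#'   [system_model()].
#' @export
make_center_cv <- function(idx, n_points) {
  stopifnot(all(idx >= 1), all(idx <= n_points))
  J <- matrix(0, 3, 3 * n_points)
  for (ax in 1:3) J[ax, (idx - 1) * 3 + ax] <- 1 / length(idx)
  list(cv = function(x) as.numeric(J %*% x),
       jacobian = function(x) J)
}

#' Coarse harmonic-network surrogate of the synthetic dimer
#'
#' An elastic network on the Calpha atoms of a [build_dimer_model()]
#' structure (springs between all pairs within `cutoff`, at their reference
#' lengths), with geometric-center collective variables over the HAMP, DHp
#' and per-chain CA residue sets. A desk-scale stand-in for the all-atom
#' protein in TAMD experiments.
#'
#' @param structure an `hk_structure` (reference geometry).
#' @param cutoff elastic-network cutoff (A).
#' @param k_en spring constant, kcal/(mol A^2).
#' @param preset domain preset for the CV groups, see [domain_presets()].
#' @return List: `system` (a [system_model()]), `x0` (flattened reference
#'   coordinates), `cv_names`.
#' @export
sys_bundle_network <- function(structure, cutoff = 10, k_en = 1,
                               preset = "methods") {
  ca_sel <- atom_select(structure, calpha = TRUE)
  xyz0 <- coords(structure)[ca_sel, , drop = FALSE]
  n <- nrow(xyz0)
  at <- structure$atoms[ca_sel, ]
  d0 <- as.matrix(stats::dist(xyz0))
  pairs <- which(upper.tri(d0) & d0 < cutoff & d0 > 1e-6, arr.ind = TRUE)
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  len0 <- d0[pairs]

  p <- domain_presets(preset)
  grp <- list(hamp = which(at$resid %in% p$hamp),
              dhp = which(at$resid %in% p$dhp),
              ca_a = which(at$resid %in% p$ca & at$chain == "A"),
              ca_b = which(at$resid %in% p$ca & at$chain == "B"))
  grp <- grp[vapply(grp, length, integer(1)) > 0L]
  cvs <- lapply(grp, make_center_cv, n_points = n)
  Jall <- do.call(rbind, lapply(cvs, function(c3) c3$jacobian(NULL)))

  potential <- function(x) {
    m <- matrix(x, ncol = 3, byrow = TRUE)
    dv <- m[i1, , drop = FALSE] - m[i2, , drop = FALSE]
    d <- sqrt(rowSums(dv * dv))
    0.5 * k_en * sum((d - len0)^2)
  }
  gradient <- function(x) {
    m <- matrix(x, ncol = 3, byrow = TRUE)
    dv <- m[i1, , drop = FALSE] - m[i2, , drop = FALSE]
    d <- sqrt(rowSums(dv * dv))
    f <- k_en * (d - len0) / d    # magnitude factor per spring
    fd <- dv * f
    g <- matrix(0, n, 3)
    for (ax in 1:3) {
      acc1 <- tapply(fd[, ax], i1, sum)
      acc2 <- tapply(fd[, ax], i2, sum)
      g[as.integer(names(acc1)), ax] <- g[as.integer(names(acc1)), ax] + acc1
      g[as.integer(names(acc2)), ax] <- g[as.integer(names(acc2)), ax] - acc2
    }
    as.numeric(t(g))
  }
  sys <- system_model(
    dimension = 3 * n, potential = potential, gradient = gradient,
    cv = function(x) as.numeric(Jall %*% x),
    cv_jacobian = function(x) Jall,
    n_cv = nrow(Jall), validate = FALSE)
  x0 <- as.numeric(t(xyz0))
  # FD validation at the (generic) reference, where no spring length is zero
  g <- sys$gradient(x0 + 0.05)
  for (k in unique(round(seq(1, sys$dimension, length.out = 5L)))) {
    e <- numeric(sys$dimension); e[k] <- 1e-5
    g_fd <- (potential(x0 + 0.05 + e) - potential(x0 + 0.05 - e)) / 2e-5
    if (abs(g[k] - g_fd) / max(abs(g_fd), 1) > 1e-4)
      stop("elastic-network gradient mismatch at coordinate ", k)
  }
  list(system = sys, x0 = x0,
       cv_names = as.character(outer(c("x", "y", "z"), names(grp),
                                     function(a, b) paste(b, a, sep = "_"))))
}

#' TAMD run parameters
#'
#' Defaults follow the published protocol: spring kappa = 100
#' kcal/(mol A^2), physical friction gamma = 0.5 ps^-1, physical thermal
#' energy beta^-1 = 0.6 kcal/mol, artificial thermal energy beta_bar^-1 = 15
#' kcal/mol, time step 2 fs. The CV friction gamma_bar appears in the
#' overdamped z-equation with units energy x time / unit^2; the published
#' value "0.02 ps^-1" is a rate convention, converted here by the identity
#' mass-like factor 1 (kcal ps^2)/(mol A^2), i.e. gamma_bar = 1/0.02 = 50 in
#' engine units by default. Any value can be passed directly.
#'
#' @param kappa CV spring constant, kcal/(mol unit^2).
#' @param gamma physical friction, ps^-1.
#' @param beta_inv physical thermal energy, kcal/mol.
#' @param gamma_bar CV friction, kcal ps/(mol unit^2).
#' @param beta_bar_inv artificial thermal energy, kcal/mol.
#' @param dt time step, ps.
#' @param seed RNG seed.
#' @return A `tamd_params` list.
#' @export
tamd_params <- function(kappa = 100, gamma = 0.5, beta_inv = 0.6,
                        gamma_bar = 50, beta_bar_inv = 15,
                        dt = 0.002, seed = 1) {
  if (any(c(kappa, gamma, beta_inv, gamma_bar, beta_bar_inv, dt) <= 0))
    stop("all TAMD parameters must be positive")
  if (beta_bar_inv < beta_inv)
    warning("beta_bar_inv < beta_inv: no acceleration")
  if (gamma_bar <= kappa * dt / 2)
    stop("unstable z-dynamics: require gamma_bar > kappa * dt / 2 (got ",
         gamma_bar, " <= ", kappa * dt / 2, ")")
  structure(list(kappa = kappa, gamma = gamma, beta_inv = beta_inv,
                 gamma_bar = gamma_bar, beta_bar_inv = beta_bar_inv,
                 dt = dt, seed = as.integer(seed)),
            class = "tamd_params")
}

#' Extended TAMD potential
#'
#' `U(x, z) = V(x) + (kappa/2) ||theta(x) - z||^2`.
#'
#' @param x physical coordinates.
#' @param z CV target values.
#' @param system a [system_model()].
#' @param params a [tamd_params()].
#' @return Energy, kcal/mol.
#' @export
extended_potential <- function(x, z, system, params) {
  if (length(x) != system$dimension)
    stop("x has length ", length(x), ", system dimension is ",
         system$dimension)
  th <- system$cv(x)
  if (length(z) != length(th))
    stop("z has length ", length(z), ", system has ", length(th), " CVs")
  system$potential(x) + 0.5 * params$kappa * sum((th - z)^2)
}

# force on x under the extended potential:
# -grad V - kappa J^T (theta - z)
extended_force <- function(x, z, system, params) {
  th <- system$cv(x)
  f <- -system$gradient(x) -
    params$kappa * as.numeric(crossprod(system$cv_jacobian(x), th - z))
  list(force = f, theta = th)
}

#' Initial TAMD state
#'
#' Velocities default to zero; z defaults to theta(x).
#'
#' @param system a [system_model()].
#' @param x initial coordinates.
#' @param v initial velocities (default 0).
#' @param z initial CV targets (default theta(x)).
#' @return A `tamd_state` list with fields `x`, `v`, `z`, `t`.
#' @export
tamd_state <- function(system, x = rep(0, system$dimension), v = NULL,
                       z = NULL) {
  if (is.null(v)) v <- rep(0, system$dimension)
  if (is.null(z)) z <- system$cv(x)
  if (!all(is.finite(c(x, v, z)))) stop("non-finite initial state")
  structure(list(x = x, v = v, z = z, t = 0), class = "tamd_state")
}

#' Advance the extended system one time step
#'
#' x and v take one BAOAB Langevin step under the extended potential; z
#' takes one Euler-Maruyama step of its overdamped equation. Noise vectors
#' may be supplied (for reproducible batching); by default they are drawn
#' from the session RNG. Passing zero noise gives the deterministic limit.
#'
#' @param state a [tamd_state()].
#' @param system a [system_model()].
#' @param params a [tamd_params()].
#' @param noise_x,noise_z standard-normal draws (lengths dimension, n_cv).
#' @param force cached `extended_force()` output for the current state
#'   (optional; recomputed if missing).
#' @return Updated state, with the force at the new position attached as
#'   attribute `"force"`.
#' @export
tamd_step <- function(state, system, params, noise_x = NULL, noise_z = NULL,
                      force = NULL) {
  d <- system$dimension
  if (is.null(noise_x)) noise_x <- stats::rnorm(d)
  if (is.null(noise_z)) noise_z <- stats::rnorm(length(state$z))
  if (is.null(force)) force <- extended_force(state$x, state$z, system, params)
  dt <- params$dt
  m <- system$mass
  cf <- exp(-params$gamma * dt)
  sf <- sqrt(params$beta_inv * (1 - cf^2) / m)

  # BAOAB: B (half kick), A (half drift), O (thermostat), A, B
  v <- state$v + 0.5 * dt * force$force / m
  x <- state$x + 0.5 * dt * v
  v <- cf * v + sf * noise_x
  x <- x + 0.5 * dt * v
  # z step uses theta at the pre-step x (Euler-Maruyama on Eq 2)
  z <- state$z + (dt / params$gamma_bar) * params$kappa *
    (force$theta - state$z) +
    sqrt(2 * dt * params$beta_bar_inv / params$gamma_bar) * noise_z
  f_new <- extended_force(x, z, system, params)
  if (!all(is.finite(f_new$force)))
    stop("non-finite force at t = ", signif(state$t + dt, 6), " ps")
  v <- v + 0.5 * dt * f_new$force / m
  out <- structure(list(x = x, v = v, z = z, t = state$t + dt),
                   class = "tamd_state")
  attr(out, "force") <- f_new
  out
}

#' Run a TAMD trajectory
#'
#' Deterministic under `params$seed`. The integration loop is inlined with
#' block-pre-drawn Gaussian noise for speed; records are taken every
#' `record_every` steps (the initial state is record 0... the first record
#' is after `record_every` steps).
#'
#' @param system a [system_model()].
#' @param params a [tamd_params()].
#' @param n_steps number of integration steps (>= 1).
#' @param record_every record stride in steps.
#' @param state optional initial [tamd_state()].
#' @return List of class `tamd_record`: `t` (ps), matrices `x`, `theta`,
#'   `z` (one row per record), vector `U`, plus `params` and `final_state`.
#' @export
run_tamd <- function(system, params, n_steps, record_every = 10L,
                     state = NULL) {
  stopifnot(n_steps >= 1, record_every >= 1)
  if (is.null(state)) state <- tamd_state(system)
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  d <- system$dimension
  ncv <- length(state$z)
  dt <- params$dt
  m <- system$mass
  cf <- exp(-params$gamma * dt)
  sf <- sqrt(params$beta_inv * (1 - cf^2) / m)
  zc <- dt * params$kappa / params$gamma_bar
  zs <- sqrt(2 * dt * params$beta_bar_inv / params$gamma_bar)

  n_rec <- n_steps %/% record_every
  rec_t <- numeric(n_rec)
  rec_x <- matrix(NA_real_, n_rec, d)
  rec_th <- matrix(NA_real_, n_rec, ncv)
  rec_z <- matrix(NA_real_, n_rec, ncv)
  rec_u <- numeric(n_rec)

  x <- state$x; v <- state$v; z <- state$z; t0 <- state$t
  f <- extended_force(x, z, system, params)
  block <- 10000L
  drawn <- 0L; nx <- NULL; nz <- NULL
  ri <- 0L
  for (i in seq_len(n_steps)) {
    k <- (i - 1L) %% block + 1L
    if (k == 1L) {
      nb <- min(block, n_steps - i + 1L)
      nx <- matrix(stats::rnorm(nb * d), nb, d)
      nz <- matrix(stats::rnorm(nb * ncv), nb, ncv)
    }
    v <- v + 0.5 * dt * f$force / m
    x <- x + 0.5 * dt * v
    v <- cf * v + sf * nx[k, ]
    x <- x + 0.5 * dt * v
    z <- z + zc * (f$theta - z) + zs * nz[k, ]
    f <- extended_force(x, z, system, params)
    if (!all(is.finite(f$force)))
      stop("non-finite force at step ", i)
    v <- v + 0.5 * dt * f$force / m
    if (i %% record_every == 0L) {
      ri <- ri + 1L
      rec_t[ri] <- t0 + i * dt
      rec_x[ri, ] <- x
      rec_th[ri, ] <- f$theta
      rec_z[ri, ] <- z
      rec_u[ri] <- system$potential(x) +
        0.5 * params$kappa * sum((f$theta - z)^2)
    }
  }
  structure(list(t = rec_t, x = rec_x, theta = rec_th, z = rec_z, U = rec_u,
                 params = params,
                 final_state = structure(list(x = x, v = v, z = z,
                                              t = t0 + n_steps * dt),
                                         class = "tamd_state")),
            class = "tamd_record")
}

#' Write a TAMD record as a CSV table
#'
#' Columns: t, theta_1..theta_k, z_1..z_k, U.
#'
#' @param record a `tamd_record` from [run_tamd()].
#' @param path output file.
#' @export
write_tamd_record <- function(record, path) {
  k <- ncol(record$z)
  df <- data.frame(t = record$t)
  for (j in seq_len(k)) df[[paste0("theta_", j)]] <- record$theta[, j]
  for (j in seq_len(k)) df[[paste0("z_", j)]] <- record$z[, j]
  df$U <- record$U
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate the CV friction by the restrained-force running average
#'
#' With z clamped at `z_fixed`, physical MD is run and the running average
#' of the restraining force on each CV component,
#' `G_j(N) = (kappa / N) sum_i [theta_j(x(t_i)) - z_j]`,
#' is accumulated. A converged, small |G| indicates the spring/friction
#' combination keeps the system near the clamped targets. The standard
#' deviation of the last quarter of each curve is reported as a convergence
#' diagnostic.
#'
#' @param system a [system_model()].
#' @param params a [tamd_params()] (gamma_bar is irrelevant here; z is
#'   clamped).
#' @param z_fixed clamped CV values.
#' @param duration simulated time, ps (>= 10).
#' @param record_every sampling stride in steps.
#' @param state optional initial [tamd_state()].
#' @return List of class `gamma_bar_calibration`: `t`, matrix `G` (running
#'   averages, one column per CV), `G_final`, `last_quarter_sd`.
#' @export
calibrate_gamma_bar <- function(system, params, z_fixed, duration = 100,
                                record_every = 1L, state = NULL) {
  if (duration < 10) stop("calibration duration must be >= 10 ps")
  n_steps <- ceiling(duration / params$dt)
  if (is.null(state)) state <- tamd_state(system, z = z_fixed)
  state$z <- z_fixed
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  d <- system$dimension
  ncv <- length(z_fixed)
  dt <- params$dt
  m <- system$mass
  cf <- exp(-params$gamma * dt)
  sf <- sqrt(params$beta_inv * (1 - cf^2) / m)

  n_rec <- n_steps %/% record_every
  Gmat <- matrix(NA_real_, n_rec, ncv)
  rec_t <- numeric(n_rec)
  sum_dev <- numeric(ncv)

  x <- state$x; v <- state$v
  f <- extended_force(x, z_fixed, system, params)
  block <- 10000L
  ri <- 0L; nsamp <- 0L
  nx <- NULL
  for (i in seq_len(n_steps)) {
    k <- (i - 1L) %% block + 1L
    if (k == 1L)
      nx <- matrix(stats::rnorm(min(block, n_steps - i + 1L) * d),
                   ncol = d)
    v <- v + 0.5 * dt * f$force / m
    x <- x + 0.5 * dt * v
    v <- cf * v + sf * nx[k, ]
    x <- x + 0.5 * dt * v
    f <- extended_force(x, z_fixed, system, params)
    if (!all(is.finite(f$force))) stop("non-finite force at step ", i)
    v <- v + 0.5 * dt * f$force / m
    if (i %% record_every == 0L) {
      ri <- ri + 1L
      nsamp <- nsamp + 1L
      sum_dev <- sum_dev + (f$theta - z_fixed)
      Gmat[ri, ] <- params$kappa * sum_dev / nsamp
      rec_t[ri] <- i * dt
    }
  }
  lq <- Gmat[seq.int(floor(3 * n_rec / 4) + 1L, n_rec), , drop = FALSE]
  structure(list(t = rec_t, G = Gmat, G_final = Gmat[n_rec, ],
                 last_quarter_sd = apply(lq, 2, stats::sd)),
            class = "gamma_bar_calibration")
}

#' Free-energy profile from a z-trajectory
#'
#' `F(z) = -beta_bar_inv * log p(z)` from a histogram of the recorded CV
#' targets, shifted so the minimum is zero. One-dimensional z only. Bins
#' interior to the sampled range that receive no samples are masked (NA)
#' with a warning.
#'
#' @param z_record numeric vector of z samples (>= 1e4).
#' @param bins number of histogram bins.
#' @param beta_bar_inv artificial thermal energy used in the run, kcal/mol.
#' @return data.frame with `z` (bin centers) and `F` (kcal/mol).
#' @export
free_energy_estimate <- function(z_record, bins = 50, beta_bar_inv = 15) {
  z <- as.numeric(z_record)
  if (length(z) < 1e4)
    stop("need at least 1e4 samples for a free-energy estimate (got ",
         length(z), ")")
  edges <- seq(min(z), max(z), length.out = bins + 1L)
  counts <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  occupied <- which(counts > 0)
  interior_empty <- counts == 0 &
    seq_along(counts) > min(occupied) & seq_along(counts) < max(occupied)
  if (any(interior_empty))
    warning(sum(interior_empty),
            " empty bin(s) interior to the sampled range masked")
  F <- -beta_bar_inv * log(counts / sum(counts))
  F[counts == 0] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  data.frame(z = centers, F = F)
}
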