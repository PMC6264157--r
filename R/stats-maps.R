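# Joint descriptor distributions, local maxima, and the correlation report
# connecting HAMP helix parameters to the theta_HAD/theta_HA*D ratio.

#' Joint distribution of two descriptor series
#'
#' A normalized density on a regular grid covering the data plus a 5%
#' margin, from either a 2D histogram (default; Scott-rule bin counts) or a
#' Gaussian kernel estimate (`MASS::kde2d`, Scott bandwidths).
#'
#' @param x,y numeric vectors (or [descriptor_series()]) of equal length
#'   >= 100.
#' @param method "histogram" or "kde".
#' @param resolution grid size per axis; `NULL` picks the Scott rule
#'   (histogram) or 101 (kde).
#' @param names_xy length-2 character, axis labels.
#' @param margin fractional range padding on each side.
#' @return Object of class `joint_distribution`: `x`, `y` (grid centers),
#'   `density` (matrix, x by y), `bandwidth` (grid step per axis),
#'   `method`, `names`.
#' @export
joint_distribution <- function(x, y, method = c("histogram", "kde"),
                               resolution = NULL,
                               names_xy = c("x", "y"), margin = 0.05) {
  method <- match.arg(method)
  if (is.data.frame(x)) x <- x$value
  if (is.data.frame(y)) y <- y$value
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 100) stop("need at least 100 paired samples (got ", n, ")")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("zero-variance axis: joint distribution undefined")

  pad <- function(v) {
    r <- range(v); w <- diff(r)
    r + c(-1, 1) * margin * w
  }
  rx <- pad(x); ry <- pad(y)

  if (method == "histogram") {
    if (is.null(resolution)) {
      # bivariate normal-reference bin width (n^(-1/4) exponent for d = 2),
      # capped to a sane grid
      nb <- function(v, r) {
        h <- 3.49 * stats::sd(v) / n^(1 / 4)
        max(5L, min(200L, ceiling(diff(r) / h)))
      }
      res_x <- nb(x, rx); res_y <- nb(y, ry)
    } else res_x <- res_y <- as.integer(resolution)
    bx <- seq(rx[1], rx[2], length.out = res_x + 1L)
    by <- seq(ry[1], ry[2], length.out = res_y + 1L)
    ix <- findInterval(x, bx, rightmost.closed = TRUE)
    iy <- findInterval(y, by, rightmost.closed = TRUE)
    dens <- matrix(0, res_x, res_y)
    for (k in seq_len(n)) dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + 1
    cell <- diff(bx)[1] * diff(by)[1]
    dens <- dens / (n * cell)
    gx <- (bx[-1] + bx[-length(bx)]) / 2
    gy <- (by[-1] + by[-length(by)]) / 2
    bw <- c(diff(bx)[1], diff(by)[1])
  } else {
    if (is.null(resolution)) resolution <- 101L
    h <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)  # Scott, 2D
    kd <- MASS::kde2d(x, y, h = h * 4, n = resolution,
                      lims = c(rx, ry))  # kde2d's h is 4x the sd-bandwidth
    cell <- diff(kd$x)[1] * diff(kd$y)[1]
    dens <- kd$z / (sum(kd$z) * cell)
    gx <- kd$x; gy <- kd$y
    bw <- h
  }
  structure(list(x = gx, y = gy, density = dens, bandwidth = bw,
                 method = method, names = names_xy, n = n),
            class = "joint_distribution")
}

#' Local maxima of a joint distribution
#'
#' Grid cells whose density strictly exceeds all eight neighbors and is at
#' least `min_prominence` times the global maximum. Maxima closer than one
#' bandwidth (grid step) in both axes are merged, keeping the denser one.
#' Results are sorted by density, descending.
#'
#' @param jd a [joint_distribution()].
#' @param min_prominence fraction of the global peak density.
#' @return data.frame with columns `x`, `y`, `density`.
#' @export
local_maxima <- function(jd, min_prominence = 0.2) {
  d <- jd$density
  nx <- nrow(d); ny <- ncol(d)
  if (nx < 5L || ny < 5L) stop("density grid must be at least 5x5")
  floor_d <- min_prominence * max(d)
  hits <- list()
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- d[i, j]
    if (v < floor_d) next
    nb <- d[(i - 1):(i + 1), (j - 1):(j + 1)]
    nb[2, 2] <- -Inf
    if (v > max(nb))
      hits[[length(hits) + 1L]] <- c(jd$x[i], jd$y[j], v)
  }
  if (length(hits) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), density = numeric(0)))
  m <- do.call(rbind, hits)
  m <- m[order(m[, 3], decreasing = TRUE), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(m))) {
      if (j <= i || !keep[j]) next
      if (abs(m[j, 1] - m[i, 1]) <= jd$bandwidth[1] + 1e-12 &&
          abs(m[j, 2] - m[i, 2]) <= jd$bandwidth[2] + 1e-12)
        keep[j] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(x = m[, 1], y = m[, 2], density = m[, 3])
}

#' Correlation report: HAMP parameters vs the angle ratio
#'
#' For every descriptor column paired with the `ratio` column: the joint
#' distribution, its local maxima, and a monotonic-trend summary of the
#' maxima (Spearman correlation of ratio-at-maxima against
#' parameter-at-maxima; reported as NA with fewer than 3 maxima).
#'
#' @param table data.frame of per-frame descriptors including a ratio
#'   column.
#' @param ratio_col name of the ratio column.
#' @param params columns to pair with the ratio (default: all other numeric
#'   columns).
#' @param method,resolution,min_prominence passed to
#'   [joint_distribution()] / [local_maxima()].
#' @return List of class `correlation_report`, one element per parameter:
#'   `distribution`, `maxima`, `spearman_rho`, `trend_sign`.
#' @export
correlation_report <- function(table, ratio_col = "ratio", params = NULL,
                               method = "histogram", resolution = NULL,
                               min_prominence = 0.2) {
  if (!ratio_col %in% names(table))
    stop("missing ratio column '", ratio_col, "'")
  if (is.null(params)) {
    num <- vapply(table, is.numeric, logical(1))
    params <- setdiff(names(table)[num],
                      c(ratio_col, "frame", "time_ps"))
  }
  if (length(params) == 0L)
    stop("no HAMP parameter columns to pair with the ratio")
  out <- lapply(params, function(p) {
    jd <- joint_distribution(table[[p]], table[[ratio_col]],
                             method = method, resolution = resolution,
                             names_xy = c(p, ratio_col))
    mx <- local_maxima(jd, min_prominence = min_prominence)
    rho <- if (nrow(mx) >= 3L)
      suppressWarnings(stats::cor(mx$x, mx$y, method = "spearman"))
    else NA_real_
    list(parameter = p, distribution = jd, maxima = mx,
         spearman_rho = rho,
         trend_sign = if (is.na(rho)) NA_integer_ else as.integer(sign(rho)))
  })
  names(out) <- params
  class(out) <- "correlation_report"
  out
}

#' Write a joint-distribution density grid as CSV
#'
#' Long format: columns `x`, `y`, `density`.
#'
#' @param jd a [joint_distribution()].
#' @param path output file.
#' @export
write_density_csv <- function(jd, path) {
  df <- expand.grid(x = jd$x, y = jd$y)
  df$density <- as.numeric(jd$density)
  names(df)[1:2] <- jd$names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
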