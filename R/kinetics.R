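#' Tracer autocorrelation of micelle size
#'
#' For each tracer chain, `N(t)` is the aggregation number of the micelle
#' the chain resides in at time `t` (1 when free). The autocorrelation
#' `C(t) = (<N(t0 + t) N(t0)> - <N(t0)>^2) / (<N(t0)^2> - <N(t0)>^2)`
#' is averaged over all tracers and all time origins `t0`. `C(0) = 1` by
#' construction and the decay of `C` measures micelle exchange dynamics.
#'
#' @param tracer_N Matrix of micelle sizes, tracers in rows, equally spaced
#'   frames in columns.
#' @return Numeric vector `C` of length `ncol(tracer_N)` (lags 0, 1, ...).
#'   An error is raised when the series has zero variance (constant `N`).
#' @export
tracer_autocorrelation <- function(tracer_N) {
  tracer_N <- as.matrix(tracer_N)
  nt <- ncol(tracer_N)
  mu <- mean(tracer_N)
  v <- mean(tracer_N^2) - mu^2
  if (v <= 0) stop("degenerate series: N(t) is constant, C(t) undefined")
  C <- numeric(nt)
  for (lag in 0:(nt - 1)) {
    a <- tracer_N[, seq_len(nt - lag), drop = FALSE]
    b <- tracer_N[, seq_len(nt - lag) + lag, drop = FALSE]
    C[lag + 1] <- (mean(a * b) - mu^2) / v
  }
  C
}

#' Relaxation time from an autocorrelation curve
#'
#' The first crossing of `C(t)` below `1/e` (0.3679), linearly interpolated
#' between samples.
#'
#' @param C Autocorrelation values at the sample times.
#' @param times Sample times (defaults to lags `0:(length(C)-1)`).
#' @param threshold Crossing level (default `exp(-1)`).
#' @return The crossing time, or `NA` with a warning when the curve never
#'   relaxes below the threshold (the series is too short).
#' @export
relaxation_time <- function(C, times = seq_along(C) - 1,
                            threshold = exp(-1)) {
  below <- which(C < threshold)
  if (!length(below)) {
    warning("C(t) never crosses ", signif(threshold, 3),
            ": not relaxed (series too short)")
    return(NA_real_)
  }
  k <- below[1]
  if (k == 1) return(times[1])
  # linear interpolation between samples k-1 and k
  t0 <- times[k - 1]; t1 <- times[k]
  c0 <- C[k - 1]; c1 <- C[k]
  t0 + (c0 - threshold) / (c0 - c1) * (t1 - t0)
}

#' Mean squared displacement and diffusion exponent
#'
#' MSD over all tracers and all time origins from unwrapped coordinates,
#' with the scaling exponent `alpha` of `MSD ~ t^alpha` fitted by least
#' squares on `log MSD` vs `log t`. The default fit window is the last
#' temporal decade of the curve, where the asymptotic scaling has set in.
#'
#' @param coords List of n x 3 unwrapped coordinate matrices, one per frame
#'   (equally spaced), or a 3-d array `[bead, axis, frame]`.
#' @param times Frame times.
#' @param tracer_ids Optional row indices of the tracer beads (default all).
#' @param fit_window Range of lag times used in the fit; default
#'   `c(max(t)/10, max(t))`.
#' @return List with `msd` (data frame `t`, `msd`), `alpha`, `prefactor`,
#'   `window`. `alpha` is `NA` (with a warning) for static input.
#' @export
cargo_msd <- function(coords, times, tracer_ids = NULL, fit_window = NULL) {
  if (is.array(coords) && length(dim(coords)) == 3) {
    coords <- lapply(seq_len(dim(coords)[3]), function(k) coords[, , k])
  }
  nf <- length(coords)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(tracer_ids)) tracer_ids <- seq_len(nrow(coords[[1]]))
  X <- vapply(coords, function(m) m[tracer_ids, 1], numeric(length(tracer_ids)))
  Y <- vapply(coords, function(m) m[tracer_ids, 2], numeric(length(tracer_ids)))
  Z <- vapply(coords, function(m) m[tracer_ids, 3], numeric(length(tracer_ids)))
  X <- matrix(X, ncol = nf); Y <- matrix(Y, ncol = nf); Z <- matrix(Z, ncol = nf)
  lags <- seq_len(nf - 1)
  msd <- vapply(lags, function(lag) {
    i0 <- seq_len(nf - lag)
    mean((X[, i0 + lag] - X[, i0])^2 +
           (Y[, i0 + lag] - Y[, i0])^2 +
           (Z[, i0 + lag] - Z[, i0])^2)
  }, 0)
  dt <- times[2] - times[1]
  tl <- lags * dt
  out <- list(msd = data.frame(t = tl, msd = msd))
  if (all(msd <= 0)) {
    warning("MSD is identically zero (static beads): alpha undefined")
    out$alpha <- NA_real_
    out$prefactor <- NA_real_
    out$window <- c(NA_real_, NA_real_)
    return(out)
  }
  if (is.null(fit_window)) fit_window <- c(max(tl) / 10, max(tl))
  sel <- tl >= fit_window[1] & tl <= fit_window[2] & msd > 0
  fit <- stats::lm(log(msd[sel]) ~ log(tl[sel]))
  out$alpha <- unname(stats::coef(fit)[2])
  out$prefactor <- exp(unname(stats::coef(fit)[1]))
  out$window <- fit_window
  out
}

#' Cargo release time series
#'
#' The fraction of initially encapsulated cargo molecules that are currently
#' free, per frame. Re-encapsulation (a released molecule entering any
#' micelle again) decreases the fraction, so the series counts the current
#' state rather than a running maximum.
#'
#' @param encapsulated Logical matrix: cargo molecules in rows, frames in
#'   columns; `TRUE` when the molecule is encapsulated at that frame. Row
#'   names are cargo molecule ids.
#' @param times Frame times.
#' @return A data frame with `t`, `released` (fraction), and
#'   `encapsulated_count`.
#' @export
release_series <- function(encapsulated, times = NULL) {
  encapsulated <- as.matrix(encapsulated)
  init <- encapsulated[, 1]
  if (!any(init)) stop("no cargo is encapsulated at the first frame")
  sub <- encapsulated[init, , drop = FALSE]
  released <- colMeans(!sub)
  if (is.null(times)) times <- seq_len(ncol(encapsulated)) - 1
  data.frame(t = times, released = released,
             encapsulated_count = colSums(sub))
}

#' Korsmeyer-Peppas fit of a release curve
#'
#' Fits `M_t / M_inf = k t^n` to the initial part of the release curve
#' (points with release fraction at most `fit_window`, the customary 60%)
#' by nonlinear least squares, with a log-log linear fit as the starting
#' value. An exponent `0.45 < n < 1` labels the release non-Fickian
#' (diffusion plus carrier relaxation/erosion contribute).
#'
#' @param release Data frame with columns `t` and `released` (as returned by
#'   [release_series()]), or two vectors via `t` and `released`.
#' @param fit_window Upper release fraction used for fitting (default 0.60).
#' @return A `kp_fit` object: list with `k`, `n`, `residual` (RMS), the
#'   number of points used, `fit_window`, and `mechanism` (text label).
#' @export
kp_fit <- function(release, fit_window = 0.60) {
  t <- release$t
  y <- release$released
  keep <- y <= fit_window & t > 0
  if (sum(keep & y > 0) < 5) {
    stop("fit failure: need at least 5 positive release points at or below ",
         fit_window)
  }
  t <- t[keep]; y <- y[keep]
  pos <- y > 0
  start_fit <- stats::lm(log(y[pos]) ~ log(t[pos]))
  start <- list(k = exp(unname(stats::coef(start_fit)[1])),
                n = unname(stats::coef(start_fit)[2]))
  if (!is.finite(start$k) || start$k <= 0) start$k <- 1e-3
  if (!is.finite(start$n) || start$n <= 0) start$n <- 0.8
  fit <- minpack.lm::nlsLM(y ~ k * t^n, start = start,
                           lower = c(k = 1e-12, n = 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  n <- unname(cf["n"])
  mech <- if (n <= 0.45) "Fickian (case I)" else
    if (n < 1) "non-Fickian (anomalous)" else
      if (n == 1) "case II (boundary)" else "super case II"
  structure(list(k = unname(cf["k"]), n = n,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 n_points = length(t), fit_window = fit_window,
                 mechanism = mech),
            class = "kp_fit")
}

#' @export
print.kp_fit <- function(x, ...) {
  cat("<kp_fit> k = ", signif(x$k, 4), " tau^-n, n = ", signif(x$n, 4),
      " (", x$mechanism, "), RMS residual = ", signif(x$residual, 3),
      " on ", x$n_points, " points\n", sep = "")
  invisible(x)
}

#' Per-chain micelle-size series from a trajectory
#'
#' Runs [stillinger_clusters()] on every frame and returns the tracer matrix
#' expected by [tracer_autocorrelation()]: for each copolymer chain the
#' aggregation number of its micelle (1 when free).
#'
#' @param traj A `cg_trajectory` from [run_protocol()].
#' @param cutoff Stillinger contact cutoff.
#' @return List with `N` (chains x frames matrix), `times`, and
#'   `assignments` (the per-frame `micelle_assignment`s).
#' @export
tracer_size_series <- function(traj, cutoff = 1.5) {
  states <- trajectory_states(traj)
  assignments <- lapply(states, stillinger_clusters, cutoff = cutoff)
  chains <- names(assignments[[1]]$chain_labels)
  N <- vapply(assignments, function(a) {
    sizes <- vapply(a$micelles, function(m) length(m$chains), 0L)
    lab <- a$chain_labels[chains]
    ifelse(is.na(lab), 1L, sizes[lab])
  }, integer(length(chains)))
  N <- matrix(N, nrow = length(chains),
              dimnames = list(chains, NULL))
  list(N = N, times = vapply(traj$frames, `[[`, 0, "time"),
       assignments = assignments)
}

#' Encapsulation state per cargo molecule over a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param cutoff Stillinger contact cutoff.
#' @return Logical matrix (cargo molecules x frames) plus frame times, ready
#'   for [release_series()].
#' @export
encapsulation_series <- function(traj, cutoff = 1.5) {
  states <- trajectory_states(traj)
  assignments <- lapply(states, stillinger_clusters, cutoff = cutoff)
  ids <- names(assignments[[1]]$cargo_in)
  M <- vapply(assignments, function(a) a$cargo_in[ids],
              logical(length(ids)))
  M <- matrix(M, nrow = length(ids), dimnames = list(ids, NULL))
  list(encapsulated = M, times = vapply(traj$frames, `[[`, 0, "time"),
       assignments = assignments)
}

# Materialize per-frame cg_system snapshots from a trajectory (bonds/types
# fall back to the final state for reaction-free runs).
trajectory_states <- function(traj) {
  lapply(traj$frames, function(fr) {
    st <- traj$state
    st$pos <- fr$pos
    st$img <- fr$img
    st$time <- fr$time
    if (!is.null(fr$bonds)) st$bonds <- fr$bonds
    if (!is.null(fr$types)) st$types <- fr$types
    st
  })
}
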