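# Trajectory observables: velocity autocorrelation and its power spectrum,
# diffusion constants from mean-square displacements, barrier-crossing
# counts on the double well, and energy histograms.

.traj_matrix <- function(x) {
  # frames x atoms x 3 array (or frames x d matrix) -> frames x (3*atoms)
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3) {
    d <- dim(x)
    return(matrix(x, d[1], d[2] * d[3]))
  }
  stop("expected a frames x atoms x 3 array or a frames x d matrix")
}

#' Velocity autocorrelation function
#'
#' C(l dt) averaged over atoms and all time origins:
#' C(l) = < v(t0) . v(t0 + l dt) > where the dot product runs over the three
#' Cartesian components of one atom, and the average runs over atoms and
#' origins.  C(0) is the mean squared velocity (3 kB T / m at equilibrium).
#'
#' @param velocities frames x atoms x 3 array (e.g. an `sg_run`'s
#'   `vel_traj`), or a frames x d matrix of one atom's components.
#' @param dt Time between frames (ps).
#' @param max_lag Largest lag (in frames, < number of frames).
#' @return Data frame with `t` (ps) and `C` (A^2/ps^2).
#' @export
vacf <- function(velocities, dt, max_lag) {
  V <- .traj_matrix(velocities)
  M <- nrow(V)
  if (M < 2) stop("need at least 2 frames")
  if (max_lag >= M) stop("max_lag must be smaller than the series length")
  n_atoms <- ncol(V) / 3
  C <- vapply(0:max_lag, function(l) {
    sum(V[seq_len(M - l), , drop = FALSE] *
          V[seq_len(M - l) + l, , drop = FALSE]) / ((M - l) * n_atoms)
  }, numeric(1))
  data.frame(t = (0:max_lag) * dt, C = C)
}

#' Power spectrum of the velocity autocorrelation
#'
#' Discrete version of rho(omega) = integral C(t) exp(-i omega t) dt: the
#' VACF is windowed (Hann by default), embedded symmetrically (C(-t) =
#' C(t)), zero-padded and Fourier transformed, so rho is real, symmetric in
#' +/- omega, and rho(0) equals twice the numerical integral of the
#' windowed C over t >= 0.  The zero-frequency density is proportional to
#' the diffusion constant (rho(0) = 6 D in three dimensions).
#'
#' @param C VACF values on a uniform grid (vector, or the data frame from
#'   [vacf()]).
#' @param dt Grid spacing of the VACF (ps).
#' @param pad Zero-padding factor (>= 1) controlling spectral resolution.
#' @param window "hann" or "none".
#' @return An object of class `sg_spectrum`: `omega` (angular frequency,
#'   1/ps, up to the Nyquist limit), `density` (A^2/ps), the input `vacf`,
#'   the `windowed` VACF actually transformed, and the transform metadata
#'   (`dt`, `n_pad`, `window`).
#' @export
power_spectrum <- function(C, dt, pad = 4, window = c("hann", "none")) {
  window <- match.arg(window)
  if (is.data.frame(C)) C <- C$C
  M <- length(C)
  if (M < 2) stop("need at least 2 VACF points")
  w <- if (window == "hann" && M > 1)
    0.5 * (1 + cos(pi * (0:(M - 1)) / (M - 1))) else rep(1, M)
  x <- C * w
  n_pad <- max(2L * M, as.integer(pad) * (2L * M - 1L))
  sym <- numeric(n_pad)
  sym[1:M] <- x
  sym[n_pad - seq_len(M - 1) + 1] <- x[2:M] # circular symmetric embedding
  dens <- dt * Re(fft(sym))
  half <- seq_len(n_pad %/% 2 + 1)
  structure(list(omega = 2 * pi * (half - 1) / (n_pad * dt),
                 density = dens[half], vacf = C, windowed = x, dt = dt,
                 n_pad = n_pad, window = window),
            class = "sg_spectrum")
}

#' @export
print.sg_spectrum <- function(x, ...) {
  cat("<sg_spectrum> ", length(x$vacf), " VACF points, dt = ", x$dt,
      " ps, ", x$window, " window, padded to ", x$n_pad, "\n", sep = "")
  cat(sprintf("  rho(0) = %.5g A^2/ps (= 6 D in 3-D)\n", x$density[1]))
  invisible(x)
}

#' @export
plot.sg_spectrum <- function(x, xlim = NULL, ...) {
  plot(x$omega, x$density, type = "l", xlab = "omega (1/ps)",
       ylab = "rho(omega) (A^2/ps)", xlim = xlim, ...)
  invisible(x)
}

#' Integrated spectral density over a frequency band
#'
#' @param spectrum An `sg_spectrum`.
#' @param lo,hi Band limits (angular frequency, 1/ps).
#' @return The trapezoidal integral of the density over `[lo, hi]`.
#' @export
spectrum_band <- function(spectrum, lo, hi) {
  i <- which(spectrum$omega >= lo & spectrum$omega <= hi)
  if (length(i) < 2) stop("band contains fewer than 2 spectral points")
  om <- spectrum$omega[i]; de <- spectrum$density[i]
  sum(diff(om) * (head(de, -1) + tail(de, -1)) / 2)
}

#' Diffusion constant from the mean-square displacement
#'
#' Computes MSD(t) over a grid of lags (averaged over atoms and time
#' origins) from unwrapped coordinates and fits MSD = 6 D t over a window of
#' intermediate lags, avoiding both the ballistic regime and the poorly
#' averaged long-lag tail.
#'
#' @param positions frames x atoms x 3 array of unwrapped positions.
#' @param dt Time between frames (ps).
#' @param fit_range Fractions of the maximum lag bounding the fit window.
#' @param n_lags Number of lag points evaluated.
#' @param box Optional box edge (A): consecutive-frame jumps larger than
#'   box/2 trigger a wrapped-coordinates warning.
#' @return List with `D` (A^2/ps), the `msd` data frame, the fit `window`
#'   (ps) and `r_squared`.
#' @export
diffusion_constant <- function(positions, dt, fit_range = c(0.1, 0.5),
                               n_lags = 200, box = NULL) {
  P <- .traj_matrix(positions)
  M <- nrow(P)
  if (M < 10) stop("need at least 10 frames for an MSD fit")
  n_atoms <- ncol(P) / 3
  if (!is.null(box) && max(abs(diff(P))) > box / 2)
    warning("consecutive-frame jumps exceed box/2: positions appear ",
            "wrapped; unwrap before computing MSD")
  max_lag <- M - 1L
  lags <- unique(pmax(1L, round(seq(1, max_lag, length.out = n_lags))))
  msd <- vapply(lags, function(l) {
    d <- P[seq_len(M - l) + l, , drop = FALSE] - P[seq_len(M - l), , drop = FALSE]
    sum(d * d) / ((M - l) * n_atoms)
  }, numeric(1))
  tt <- lags * dt
  sel <- tt >= fit_range[1] * max_lag * dt & tt <= fit_range[2] * max_lag * dt
  if (sum(sel) < 2) sel <- rep(TRUE, length(tt))
  fit <- lm(msd[sel] ~ tt[sel])
  list(D = unname(coef(fit)[2]) / 6,
       msd = data.frame(t = tt, msd = msd),
       window = range(tt[sel]),
       r_squared = summary(fit)$r.squared)
}

#' Count barrier crossings with a hysteresis band
#'
#' A trajectory is labelled by the last well it visited: it must leave the
#' band `barrier_y +/- hysteresis` on the far side before a crossing is
#' counted, so recrossings that only rattle inside the band are ignored.
#' The count is invariant to time reversal of the series.
#'
#' @param y Trajectory of the reaction coordinate (A).
#' @param barrier_y Barrier position; defaults require explicit input (use
#'   [sdw_barrier()] for the double well).
#' @param hysteresis Half-width of the exclusion band (A), > 0.
#' @return An object of class `sg_crossings`: `n_crossings`, `barrier_y`,
#'   `hysteresis`, and the `dwell` run-length encoding of well labels.
#' @export
count_barrier_crossings <- function(y, barrier_y, hysteresis) {
  stopifnot(hysteresis > 0)
  lab <- ifelse(y > barrier_y + hysteresis, 1L,
                ifelse(y < barrier_y - hysteresis, -1L, 0L))
  lab <- lab[lab != 0L]
  if (!length(lab)) {
    dwell <- list(lengths = integer(0), values = integer(0))
    n <- 0L
  } else {
    r <- rle(lab)
    dwell <- list(lengths = r$lengths, values = r$values)
    n <- length(r$values) - 1L
  }
  structure(list(n_crossings = n, barrier_y = barrier_y,
                 hysteresis = hysteresis, dwell = dwell),
            class = "sg_crossings")
}

#' @export
print.sg_crossings <- function(x, ...) {
  cat("<sg_crossings> ", x$n_crossings, " crossing(s) at barrier y = ",
      signif(x$barrier_y, 4), " (hysteresis ", x$hysteresis, " A)\n",
      sep = "")
  invisible(x)
}

#' Density-normalized energy histogram
#'
#' @param E Per-frame energies (kcal/mol).
#' @param breaks Number of bins or a vector of break points.
#' @return A `histogram` object (densities integrate to 1).
#' @export
energy_histogram <- function(E, breaks = 50) {
  if (!length(E)) stop("empty input")
  graphics::hist(E, breaks = breaks, plot = FALSE)
}

#' Overlap coefficient of two energy distributions
#'
#' Histograms both samples on a shared grid and returns
#' sum(min(d1, d2) * bin_width) — 1 for identical distributions, 0 for
#' disjoint ones.
#'
#' @param E1,E2 Two samples of energies.
#' @param n_bins Number of shared bins.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
histogram_overlap <- function(E1, E2, n_bins = 50) {
  if (!length(E1) || !length(E2)) stop("empty input")
  rng <- range(c(E1, E2))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h1 <- graphics::hist(E1, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(E2, breaks = breaks, plot = FALSE)
  sum(pmin(h1$density, h2$density) * diff(breaks))
}
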