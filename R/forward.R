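# Multicomponent frequency-dependent D(omega)-R1-R2 forward signal model.
#
# Each water pool (component) is an axisymmetric diffusion tensor whose
# axial/radial eigenvalues disperse from a low-frequency value to the
# high-frequency diffusivity D_0 with Lorentzian rate Gamma:
#   D(omega) = D_0 - (D_0 - D_low) / (1 + omega^2 / Gamma^2)
# plus longitudinal and transversal relaxation rates R1, R2 and a signal
# weight w. The measured signal is
#   S = sum_i w_i exp(-int b(omega):D_i(omega) domega)
#            (1 - exp(-tau_R R1_i)) exp(-tau_E R2_i).
# Frequency integrals are evaluated one-sided (stored spectra carry the
# doubling weight for omega > 0).

#' Construct a table of diffusion-relaxation components
#'
#' @param d0 high-frequency diffusivity (m^2/s).
#' @param da,dr axial/radial low-frequency diffusivities (m^2/s).
#' @param ga,gr axial/radial dispersion rates Gamma (s^-1).
#' @param theta,phi symmetry-axis polar/azimuthal angles (rad).
#' @param r1,r2 longitudinal/transversal relaxation rates (s^-1).
#' @param w signal weight (>= 0).
#' @return data.frame of class `mmd_components`.
#' @export
components <- function(d0, da, dr, ga = 1e4, gr = 1e4, theta = 0, phi = 0,
                       r1 = 1, r2 = 10, w = 1) {
  df <- data.frame(d0 = d0, da = da, dr = dr, ga = ga, gr = gr,
                   theta = theta, phi = phi, r1 = r1, r2 = r2, w = w)
  if (any(df$w < 0)) stop("negative component weight")
  if (any(df$d0 <= 0 | df$da <= 0 | df$dr <= 0)) stop("diffusivities must be > 0")
  if (any(df$ga <= 0 | df$gr <= 0)) stop("Gamma must be > 0")
  class(df) <- c("mmd_components", "data.frame")
  df
}

#' Lorentzian dispersive eigenvalue
#'
#' \eqn{D(\omega) = D_0 - (D_0 - D_{low}) / (1 + \omega^2/\Gamma^2)}:
#' equals `d_low` at omega = 0, approaches `d0` at high frequency, and sits
#' halfway at omega = Gamma.
#'
#' @param d0 high-frequency diffusivity (m^2/s).
#' @param d_low low-frequency (long-time) diffusivity (m^2/s).
#' @param gamma_rate dispersion rate Gamma (s^-1); must be > 0.
#' @param omega angular frequency (rad/s), vectorized.
#' @return diffusivity (m^2/s).
#' @export
dispersive_eigenvalue <- function(d0, d_low, gamma_rate, omega) {
  stopifnot(all(gamma_rate > 0))
  d0 - (d0 - d_low) / (1 + omega^2 / gamma_rate^2)
}

#' Unit symmetry-axis vector from polar angles
#' @param theta,phi polar and azimuthal angles (rad).
#' @return 3-vector (or n x 3 matrix when vectorized).
#' @export
axis_vector <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Frequency-dependent isotropic diffusivity and normalized anisotropy
#'
#' \eqn{D_{iso}(\omega) = (D_A(\omega) + 2 D_R(\omega))/3};
#' \eqn{D_\Delta(\omega) = (D_A(\omega) - D_R(\omega))/(3 D_{iso}(\omega))}.
#'
#' @param comp an `mmd_components` table (n rows).
#' @param omega angular frequency (rad/s), scalar.
#' @return list with vectors `d_iso`, `d_delta`, `da`, `dr`.
#' @export
iso_and_shape <- function(comp, omega) {
  da <- dispersive_eigenvalue(comp$d0, comp$da, comp$ga, omega)
  dr <- dispersive_eigenvalue(comp$d0, comp$dr, comp$gr, omega)
  d_iso <- (da + 2 * dr) / 3
  if (any(d_iso == 0)) stop("D_iso = 0")
  list(d_iso = d_iso, d_delta = (da - dr) / (3 * d_iso), da = da, dr = dr)
}

#' Diffusion attenuation exponent of one component under one spectrum
#'
#' Evaluates \eqn{\int b(\omega):D(\omega)\,d\omega} through the
#' axisymmetric decomposition
#' \eqn{\int [D_R(\omega)\,\mathrm{tr}\,b(\omega) +
#' (D_A(\omega)-D_R(\omega))\, n^T b(\omega) n]\,d\omega}, which equals the
#' full 3x3 tensor contraction.
#'
#' @param spectrum an `mmd_spectrum`.
#' @param comp a single-row `mmd_components` table.
#' @return dimensionless attenuation exponent.
#' @export
attenuation <- function(spectrum, comp) {
  if (nrow(comp) != 1) stop("attenuation() takes a single component")
  om <- spectrum$omega_grid
  da <- dispersive_eigenvalue(comp$d0, comp$da, comp$ga, om)
  dr <- dispersive_eigenvalue(comp$d0, comp$dr, comp$gr, om)
  n <- drop(axis_vector(comp$theta, comp$phi))
  bs <- spectrum$b_matrix_spectrum
  trb <- .trace_spectrum(spectrum)
  nbn <- bs[, 1, 1] * n[1]^2 + bs[, 2, 2] * n[2]^2 + bs[, 3, 3] * n[3]^2 +
    2 * (bs[, 1, 2] * n[1] * n[2] + bs[, 1, 3] * n[1] * n[3] +
           bs[, 2, 3] * n[2] * n[3])
  sum(dr * trb + (da - dr) * nbn) * spectrum$domega
}

#' Forward signal of a component mixture under a protocol
#'
#' @param protocol an `mmd_protocol` data.frame.
#' @param comp an `mmd_components` table.
#' @param spectra optional precomputed [measurement_spectra()] list; computed
#'   on the fly when NULL.
#' @return numeric vector, one non-negative signal value per measurement.
#' @export
forward_signal <- function(protocol, comp, spectra = NULL) {
  if (any(comp$w < 0)) stop("negative component weight")
  if (is.null(spectra)) spectra <- measurement_spectra(protocol)
  M <- nrow(protocol)
  beta <- matrix(0, M, nrow(comp))
  for (m in seq_len(M)) {
    if (protocol$is_b0[m]) next
    for (i in seq_len(nrow(comp)))
      beta[m, i] <- attenuation(spectra[[m]], comp[i, , drop = FALSE])
  }
  relax <- (1 - exp(-outer(protocol$tau_r, comp$r1))) *
    exp(-outer(protocol$tau_e, comp$r2))
  drop((exp(-beta) * relax) %*% comp$w)
}

#' Restriction sensitivity of a frequency band to spherical confinement
#'
#' For water confined in a sphere of diameter d, the apparent diffusivity
#' disperses with a Lorentzian rate tied to the confinement correlation
#' time; this calculator uses \eqn{\Gamma(d) = D_{free}/(d/2)^2} and scores
#' each diameter by the in-band diffusivity change
#' \eqn{[D(\omega_{hi}; d) - D(\omega_{lo}; d)] / D_{free}}. The sensitivity
#' vanishes for both very small spheres (dispersion far above the band) and
#' very large ones (dispersion far below it), with a single interior
#' maximum. The mapping is an order-of-magnitude model.
#'
#' @param d_free free diffusivity (m^2/s).
#' @param omega_lo,omega_hi band edges (Hz).
#' @param diameters sphere diameters (m).
#' @return data.frame with `diameter` and `sensitivity`.
#' @export
restriction_sensitivity <- function(d_free = 3e-9, omega_lo = 18,
                                    omega_hi = 92,
                                    diameters = seq(1e-6, 30e-6, by = 0.1e-6)) {
  stopifnot(omega_lo < omega_hi, d_free > 0)
  wlo <- 2 * pi * omega_lo
  whi <- 2 * pi * omega_hi
  sens <- vapply(diameters, function(d) {
    g <- d_free / (d / 2)^2
    (dispersive_eigenvalue(d_free, 0, g, whi) -
       dispersive_eigenvalue(d_free, 0, g, wlo)) / d_free
  }, numeric(1))
  data.frame(diameter = diameters, sensitivity = sens)
}

# fast kernel path -------------------------------------------------------

#' Reduced frequency-binned representation of a protocol's spectra
#'
#' Integrates each measurement's one-sided spectrum over a DC bin plus
#' log-spaced frequency bins so that the per-component attenuation becomes
#' a short quadrature sum; used by the inversion's inner loops. Binning is
#' exact for frequency-flat components (bin sums preserve the integrated
#' b-tensor) and a fine quadrature for Lorentzian dispersion.
#'
#' @param protocol an `mmd_protocol`.
#' @param spectra optional [measurement_spectra()] list.
#' @param n_bins number of frequency bins (including the DC bin).
#' @return object of class `mmd_kernel_grid`: `omega` (K, rad/s
#'   representative frequencies), `trw` (M x K integrated trace), `b6` (list
#'   of 6 M x K matrices: xx, yy, zz, xy, xz, yz), plus the protocol timing
#'   vectors.
#' @export
protocol_kernel <- function(protocol, spectra = NULL, n_bins = 32L) {
  if (is.null(spectra)) spectra <- measurement_spectra(protocol)
  M <- nrow(protocol)
  dwi <- which(!protocol$is_b0)
  # frequency grids scale with waveform duration, so bin edges must span
  # the union of all grids and each spectrum is binned on its own grid
  wpos_min <- min(vapply(dwi, function(i) spectra[[i]]$omega_grid[2],
                         numeric(1)))
  wmax <- max(vapply(dwi, function(i) max(spectra[[i]]$omega_grid),
                     numeric(1)))
  edges <- c(0, wpos_min / 2,
             exp(seq(log(wpos_min * 0.999), log(wmax * 1.001),
                     length.out = n_bins - 1)))
  K <- length(edges) - 1

  agg_cache <- new.env(parent = emptyenv())
  agg_for <- function(om) {
    key <- sprintf("%.9g", om[2])
    a <- agg_cache[[key]]
    if (is.null(a)) {
      bin_of <- findInterval(om, edges, rightmost.closed = TRUE)
      a <- matrix(0, length(om), K)
      a[cbind(seq_along(om), bin_of)] <- 1
      agg_cache[[key]] <- a
    }
    a
  }

  trw <- matrix(0, M, K)
  b6 <- lapply(1:6, function(s) matrix(0, M, K))
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  sum_pow <- numeric(K)
  sum_wom <- numeric(K)
  for (i in dwi) {
    sp <- spectra[[i]]
    agg <- agg_for(sp$omega_grid)
    dw <- sp$domega
    trv <- .trace_spectrum(sp)
    trw[i, ] <- crossprod(agg, trv) * dw
    sum_pow <- sum_pow + drop(crossprod(agg, trv)) * dw
    sum_wom <- sum_wom + drop(crossprod(agg, trv * sp$omega_grid)) * dw
    for (s in 1:6) {
      b6[[s]][i, ] <- crossprod(agg,
                                sp$b_matrix_spectrum[, idx[[s]][1],
                                                     idx[[s]][2]]) * dw
    }
  }
  omega_rep <- ifelse(sum_pow > 0, sum_wom / pmax(sum_pow, 1e-300),
                      (edges[-1] + edges[-(K + 1)]) / 2)
  omega_rep[1] <- 0
  structure(list(omega = omega_rep, trw = trw, b6 = b6,
                 tau_r = protocol$tau_r, tau_e = protocol$tau_e,
                 b = protocol$b, is_b0 = protocol$is_b0),
            class = "mmd_kernel_grid")
}

#' Signal kernel matrix for a set of candidate components
#'
#' Column i is the forward signal of component i with unit weight under
#' every measurement of the protocol, evaluated on the binned frequency
#' grid. The non-negative least-squares weight solve uses this matrix as its
#' design matrix.
#'
#' @param kg an `mmd_kernel_grid`.
#' @param comp an `mmd_components` table.
#' @return M x n matrix.
#' @export
kernel_matrix <- function(kg, comp) {
  om <- kg$omega
  N <- nrow(comp)
  da <- outer_disp(comp$d0, comp$da, comp$ga, om)   # K x N
  dr <- outer_disp(comp$d0, comp$dr, comp$gr, om)
  beta <- kg$trw %*% dr
  dd <- da - dr
  n <- axis_vector(comp$theta, comp$phi)
  cs <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
              2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
  for (s in 1:6) {
    beta <- beta + (kg$b6[[s]] %*% dd) * rep(cs[, s], each = nrow(beta))
  }
  relax <- (1 - exp(-outer(kg$tau_r, comp$r1))) * exp(-outer(kg$tau_e, comp$r2))
  exp(-beta) * relax
}

# K x N matrix of dispersive eigenvalues for N components on K frequencies
outer_disp <- function(d0, d_low, gamma_rate, omega) {
  K <- length(omega)
  N <- length(d0)
  lor <- 1 / (1 + outer(omega^2, gamma_rate^2, "/"))
  matrix(d0, K, N, byrow = TRUE) - lor *
    matrix(d0 - d_low, K, N, byrow = TRUE)
}
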