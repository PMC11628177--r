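# Tensor-valued gradient waveforms and their encoding spectra b(omega).
#
# A waveform is a time-resolved 3-axis gradient trace g(t) [T/m]. The
# dephasing vector q(t) = gamma * int_0^t g dt' must start and end at the
# zero vector (self-refocusing). The encoding spectrum is
#   b(omega) = (1/2pi) q(omega) q(-omega)^T
# with q(omega) the Fourier transform of q(t), and is summarized by the total
# encoding strength b, the encoding anisotropy b_Delta in [-0.5, 1], and the
# b-weighted centroid frequency omega_cent evaluated one-sided over
# omega >= 0 (the spectrum of a real gradient trace is even in omega).

#' Gyromagnetic ratio and waveform efficiency factors
#'
#' Planning constants for the cube-root duration formula
#' \eqn{T_{diff} = (b / (2 C G_{max}^2 \gamma^2))^{1/3}}: the efficiency
#' factor \eqn{C} of the waveform family decreases with frequency-modulation
#' order, so reaching the same b-value at higher encoding frequency costs
#' duration (or gradient amplitude).
#'
#' @param g_max gradient amplitude limit (T/m).
#' @param gamma gyromagnetic ratio (rad/T/s).
#' @return data.frame with columns `order` and `C`, and attributes `gamma`
#'   and `g_max`.
#' @export
efficiency_table <- function(g_max = 0.7656, gamma = 26.75e7) {
  stopifnot(g_max > 0, gamma > 0)
  tab <- data.frame(order = 0:2, C = c(5.318e-3, 2.664e-3, 1.605e-3))
  attr(tab, "gamma") <- gamma
  attr(tab, "g_max") <- g_max
  class(tab) <- c("mmd_efficiency_table", "data.frame")
  tab
}

# Azimuthal rotation count of the transverse q-components and oscillation
# count of the axial q-component, per modulation order. Chosen so that all
# q products are orthogonal Fourier modes over the sin^2 envelope (the
# b-tensor is exactly axis-diagonal) and spectral weight moves up in
# frequency with order.
.axial_cycles <- function(order) c(0L, 2L, 4L)[order + 1L]
.transverse_cycles <- function(order) c(3L, 5L, 7L)[order + 1L]

#' Generate a self-refocusing tensor-valued gradient waveform
#'
#' Builds an axisymmetric q-vector trajectory with a smooth
#' \eqn{\sin^2(\pi t/\tau)} amplitude envelope: an axial component (along z)
#' and a rotating transverse component, blended so the time-integrated
#' b-tensor has the requested encoding anisotropy `b_delta` (1 = linear,
#' 0 = spherical, -0.5 = planar). The frequency-modulation `order` multiplies
#' the axial oscillation and transverse rotation counts, shifting encoding
#' power to higher frequencies at fixed duration. The gradient trace is the
#' analytic time derivative of q, scaled so the largest per-axis amplitude
#' equals `g_max`; q(0) = q(tau) = 0 by construction.
#'
#' @param order frequency-modulation order, one of 0, 1, 2.
#' @param duration waveform duration tau (s).
#' @param b_delta target encoding anisotropy in \[-0.5, 1\].
#' @param g_max gradient amplitude limit (T/m).
#' @param n_samples number of time samples (>= 16).
#' @param gamma gyromagnetic ratio (rad/T/s).
#' @return object of class `mmd_waveform`: list with `samples` (n x 3 matrix,
#'   T/m), `dt`, `duration`, `g_max`, `order`, `b_delta_nominal`, `gamma`.
#' @export
generate_waveform <- function(order, duration, b_delta, g_max = 0.7656,
                              n_samples = 256L, gamma = 26.75e7) {
  if (!order %in% 0:2) stop("unsupported modulation order: ", order)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (n_samples < 16L) stop("duration sampled too coarsely (need >= 16 samples)")
  if (b_delta < -0.5 || b_delta > 1) stop("b_delta out of [-0.5, 1]")

  tau <- duration
  t <- seq(0, tau, length.out = n_samples)
  env <- sin(pi * t / tau)^2
  denv <- (pi / tau) * sin(2 * pi * t / tau)

  p <- .axial_cycles(order)       # axial oscillation cycles
  m <- .transverse_cycles(order)  # transverse rotation cycles
  wp <- 2 * pi * p / tau
  wm <- 2 * pi * m / tau

  # unit-amplitude q components and their analytic derivatives
  qz <- env * cos(wp * t)
  dqz <- denv * cos(wp * t) - env * wp * sin(wp * t)
  qx <- env * cos(wm * t)
  dqx <- denv * cos(wm * t) - env * wm * sin(wm * t)
  qy <- env * sin(wm * t)
  dqy <- denv * sin(wm * t) + env * wm * cos(wm * t)

  # blend axial/transverse so eigenvalue fractions hit the target b_delta:
  # lambda_par/b = (1 + 2 b_delta)/3, lambda_perp/b = (1 - b_delta)/3
  i_par <- pracma::trapz(t, qz^2)
  i_perp <- pracma::trapz(t, qx^2)
  a_z <- sqrt((1 + 2 * b_delta) / 3 / i_par)
  a_t <- sqrt((1 - b_delta) / 3 / i_perp)

  g <- cbind(a_t * dqx, a_t * dqy, a_z * dqz) / gamma
  peak <- max(abs(g))
  g <- g * (g_max / peak)

  structure(list(samples = g, dt = t[2] - t[1], duration = tau,
                 g_max = g_max, order = as.integer(order),
                 b_delta_nominal = b_delta, gamma = gamma),
            class = "mmd_waveform")
}

#' @export
print.mmd_waveform <- function(x, ...) {
  cat(sprintf("mmd_waveform: order %d, tau %.3f ms, nominal b_delta %.2f, %d samples, g_max %.4f T/m\n",
              x$order, 1e3 * x$duration, x$b_delta_nominal,
              nrow(x$samples), x$g_max))
  invisible(x)
}

#' Compute the encoding spectrum of a gradient waveform
#'
#' Integrates the dephasing vector \eqn{q(t) = \gamma \int_0^t g\,dt'},
#' verifies self-refocusing, and evaluates
#' \eqn{b(\omega) = (1/2\pi)\, q(\omega) q(-\omega)^T} on a zero-filled FFT
#' grid. The returned spectrum is one-sided (omega >= 0) with weights doubled
#' for omega > 0, so frequency integrals over the stored grid equal the
#' two-sided integrals. Scalar summaries (b, b_delta, omega_cent) are
#' attached via [summarize_spectrum()].
#'
#' @param waveform an `mmd_waveform` (or compatible list).
#' @param zero_fill_factor zero-fill multiple of the record length (>= 1;
#'   >= 4 recommended for stable centroid estimates).
#' @param refocus_tol reject waveforms with |q(tau)| / max|q| above this.
#' @return object of class `mmd_spectrum`: `omega_grid` (rad/s),
#'   `b_matrix_spectrum` (K x 3 x 3, one-sided spectral density including the
#'   doubling weight), `q_time` (n x 3, rad/m), `b` (s/m^2), `b_tensor`
#'   (3 x 3), `b_delta`, `omega_cent` (rad/s), `b_time` (time-domain b).
#' @export
compute_spectrum <- function(waveform, zero_fill_factor = 4L,
                             refocus_tol = 1e-9) {
  g <- waveform$samples
  dt <- waveform$dt
  gamma <- if (!is.null(waveform$gamma)) waveform$gamma else 26.75e7
  if (zero_fill_factor < 1) stop("zero_fill_factor must be >= 1")
  n <- nrow(g)

  tvec <- seq(0, by = dt, length.out = n)
  q <- gamma * pracma::cumtrapz(tvec, g)
  qend <- sqrt(sum(q[n, ]^2))
  qmax <- max(sqrt(rowSums(q^2)))
  if (qmax == 0) stop("zero waveform")
  if (qend / qmax > refocus_tol)
    stop(sprintf("waveform is not self-refocusing: |q(tau)|/max|q| = %.3g (tol %.3g)",
                 qend / qmax, refocus_tol))

  nfft <- 2^ceiling(log2(zero_fill_factor * n))
  qpad <- rbind(q, matrix(0, nfft - n, 3))
  Q <- mvfft(qpad) * dt                     # q(omega), rad/m * s
  k_pos <- seq_len(nfft / 2 + 1)            # one-sided bins incl. DC, Nyquist
  omega <- 2 * pi * (k_pos - 1) / (nfft * dt)
  dw <- 2 * pi / (nfft * dt)

  wgt <- rep(2, length(k_pos))
  wgt[1] <- 1
  wgt[length(k_pos)] <- 1
  bspec <- array(0, dim = c(length(k_pos), 3, 3))
  Qp <- Q[k_pos, , drop = FALSE]
  for (a in 1:3) for (b in a:3) {
    v <- Re(Qp[, a] * Conj(Qp[, b])) / (2 * pi) * wgt
    bspec[, a, b] <- v
    bspec[, b, a] <- v
  }

  b_tensor <- apply(bspec, c(2, 3), sum) * dw
  b_time <- sum(rowSums(q^2)) * dt - dt * (sum(q[1, ]^2) + sum(q[n, ]^2)) / 2

  spec <- structure(list(omega_grid = omega, b_matrix_spectrum = bspec,
                         q_time = q, dt = dt, domega = dw,
                         b_tensor = b_tensor, b_time = b_time),
                    class = "mmd_spectrum")
  s <- summarize_spectrum(spec)
  spec$b <- s$b
  spec$b_delta <- s$b_delta
  spec$omega_cent <- s$omega_cent
  spec
}

#' Scalar summaries of an encoding spectrum
#'
#' `b` is the trace of the frequency-integrated spectrum; `b_delta` is the
#' normalized anisotropy of the b-tensor with eigenvalues ordered by the
#' convention |bZZ - b/3| > |bXX - b/3| > |bYY - b/3|, giving
#' \eqn{b_\Delta = (b_{ZZ} - (b_{YY} + b_{XX})/2)/b}; `omega_cent` is the
#' trace-b(omega)-weighted centroid over omega >= 0 (the two-sided first
#' moment of an even spectrum vanishes identically, so the one-sided
#' convention is the meaningful one).
#'
#' @param spectrum an `mmd_spectrum`.
#' @return list with `b` (s/m^2), `b_delta` (NA when b = 0), `omega_cent`
#'   (rad/s).
#' @export
summarize_spectrum <- function(spectrum) {
  bt <- spectrum$b_tensor
  trb <- .trace_spectrum(spectrum)
  b <- sum(trb) * spectrum$domega
  if (b <= 0) return(list(b = 0, b_delta = NA_real_, omega_cent = NA_real_))
  ev <- eigen(bt, symmetric = TRUE, only.values = TRUE)$values
  ord <- order(abs(ev - b / 3), decreasing = TRUE)  # ZZ, XX, YY
  bzz <- ev[ord[1]]; bxx <- ev[ord[2]]; byy <- ev[ord[3]]
  b_delta <- (bzz - (byy + bxx) / 2) / b
  omega_cent <- sum(spectrum$omega_grid * trb) / sum(trb)
  list(b = b, b_delta = b_delta, omega_cent = omega_cent)
}

.trace_spectrum <- function(spectrum) {
  bs <- spectrum$b_matrix_spectrum
  bs[, 1, 1] + bs[, 2, 2] + bs[, 3, 3]
}

#' Plan the waveform duration for a target b-value
#'
#' Closed-form inversion of the cubic growth of b with duration at fixed
#' waveform shape and amplitude:
#' \eqn{T_{diff} = (b / (2 C G_{max}^2 \gamma^2))^{1/3}}, rounded to the
#' nearest millisecond.
#'
#' @param b_target target b-value (s/m^2).
#' @param order frequency-modulation order, must be present in `table`.
#' @param table an [efficiency_table()].
#' @return planned duration in seconds (an integer number of milliseconds).
#' @export
plan_duration <- function(b_target, order, table = efficiency_table()) {
  stopifnot(b_target > 0)
  i <- match(order, table$order)
  if (is.na(i)) stop("order ", order, " missing from efficiency table")
  C <- table$C[i]
  gmax <- attr(table, "g_max")
  gamma <- attr(table, "gamma")
  t_raw <- (b_target / (2 * C * gmax^2 * gamma^2))^(1 / 3)
  round(t_raw * 1e3) / 1e3
}

#' Rotate a waveform so its symmetry axis points along a direction
#'
#' The generated waveforms have their b-tensor symmetry axis along z; this
#' applies the rotation carrying z onto `direction` to the gradient trace.
#' b and b_delta are rotation invariants.
#'
#' @param waveform an `mmd_waveform`.
#' @param direction unit 3-vector.
#' @return rotated `mmd_waveform`.
#' @export
rotate_waveform <- function(waveform, direction) {
  R <- rotation_to(direction)
  out <- waveform
  out$samples <- waveform$samples %*% t(R)
  out
}

#' Rotation matrix carrying the z axis onto a direction
#' @param direction unit 3-vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_to <- function(direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction vector")
  d <- direction / nrm
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # antiparallel: rotate pi about x
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# waveform text I/O ------------------------------------------------------

#' Write / read a waveform as a plain-text time series
#'
#' Four whitespace-separated columns (time in s, gx, gy, gz in T/m) with a
#' comment header carrying dt, g_max, order, b_delta and gamma.
#'
#' @param waveform an `mmd_waveform`.
#' @param path file path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns an `mmd_waveform`.
#' @export
write_waveform <- function(waveform, path) {
  hdr <- sprintf("# mmd_waveform dt=%.12g g_max=%.12g order=%d b_delta=%.12g gamma=%.12g",
                 waveform$dt, waveform$g_max, waveform$order,
                 waveform$b_delta_nominal, waveform$gamma)
  t <- seq(0, by = waveform$dt, length.out = nrow(waveform$samples))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(cbind(t, waveform$samples), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# mmd_waveform")) stop("not a waveform file: ", path)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.e+]+", hdr))[[1]]
  vals <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, skip = 1))
  structure(list(samples = unname(m[, 2:4, drop = FALSE]), dt = vals[["dt"]],
                 duration = vals[["dt"]] * (nrow(m) - 1),
                 g_max = vals[["g_max"]], order = as.integer(vals[["order"]]),
                 b_delta_nominal = vals[["b_delta"]], gamma = vals[["gamma"]]),
            class = "mmd_waveform")
}
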