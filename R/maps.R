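# Condensation of per-voxel bootstrap ensembles into parameter maps.
#
# The mapped metrics are x in {D_iso(omega_eval), D_Delta^2(omega_eval),
# R1, R2}. For each bootstrap realization the weighted mean / variance /
# covariance of each metric over the realization's components is computed;
# the reported per-voxel value is the median of that statistic across
# realizations ("collapsed to the mean of the ensemble of solutions, then
# condensed into medians"). Frequency dependence is quantified by the
# band-edge difference rate
#   Delta_omega/2pi E[x] = (E[x](omega_max) - E[x](omega_min)) /
#                          ((omega_max - omega_min)/2pi),
# the (D_iso, D_Delta^2) plane is partitioned into three bins
# (WM-like / GM-like / CSF-like), and bin 2 is further split into the two
# gray-matter pools at D_iso = 0.5e-9 m^2/s.

.metric_names <- c("d_iso", "d_delta2", "r1", "r2")

# weighted per-realization metric values: matrix (n_comp x 4)
.realization_metrics <- function(comp, omega) {
  sh <- iso_and_shape(comp, omega)
  cbind(d_iso = sh$d_iso, d_delta2 = sh$d_delta^2, r1 = comp$r1,
        r2 = comp$r2)
}

.wstats <- function(vals, w) {
  sw <- sum(w)
  mu <- colSums(vals * w) / sw
  ctr <- sweep(vals, 2, mu)
  cov <- crossprod(ctr * w, ctr) / sw
  list(mean = mu, cov = cov)
}

#' Default bin definition of the (D_iso, D_Delta^2) plane
#'
#' bin 1 (WM-like): D_iso < 2.5e-9 m^2/s and D_Delta^2 >= 0.25;
#' bin 2 (GM-like): D_iso < 2.5e-9 and D_Delta^2 < 0.25;
#' bin 3 (CSF-like): D_iso >= 2.5e-9. Boundary equalities are assigned so
#' the three regions partition the plane.
#'
#' @param d_iso_split D_iso boundary (m^2/s).
#' @param d_delta2_split D_Delta^2 boundary.
#' @return list of class `mmd_bins`.
#' @export
bin_definition <- function(d_iso_split = 2.5e-9, d_delta2_split = 0.25) {
  structure(list(d_iso_split = d_iso_split, d_delta2_split = d_delta2_split),
            class = "mmd_bins")
}

#' Bin index of components in the (D_iso, D_Delta^2) plane
#' @param d_iso,d_delta2 coordinates.
#' @param bins a [bin_definition()].
#' @return integer vector in 1:3.
#' @export
bin_index <- function(d_iso, d_delta2, bins = bin_definition()) {
  ifelse(d_iso >= bins$d_iso_split, 3L,
         ifelse(d_delta2 >= bins$d_delta2_split, 1L, 2L))
}

#' Per-voxel statistics bundle of a bootstrap ensemble
#'
#' @param ensemble an `mmd_ensemble`.
#' @param omega_eval_hz evaluation frequency for the omega-dependent
#'   metrics (Hz).
#' @param omega_band_hz c(lo, hi) band for the frequency-dependence rates.
#' @param bins a [bin_definition()].
#' @param gm_threshold D_iso split between the two gray-matter pools
#'   (m^2/s).
#' @return list of class `mmd_statistics`: `s0`, `mean` (E\[x\]), `var`
#'   (V\[x\]), `cov` (4 x 4 C\[x,y\]), `delta_omega` (list with mean/var/cov
#'   rates for d_iso and d_delta2), `f_bin` (3 fractions), `bin_mean`
#'   (3 x 4), `bin_delta_mean` (3 x 2), `gm1_fraction`, `gm2_fraction`,
#'   `rgb`; NULL for an empty ensemble.
#' @export
voxel_statistics <- function(ensemble, omega_eval_hz = 18,
                             omega_band_hz = c(18, 92),
                             bins = bin_definition(),
                             gm_threshold = 0.5e-9) {
  if (is.null(ensemble) || !length(ensemble$realizations)) return(NULL)
  om_eval <- 2 * pi * omega_eval_hz
  om_lo <- 2 * pi * omega_band_hz[1]
  om_hi <- 2 * pi * omega_band_hz[2]
  if (om_lo >= om_hi) stop("omega band must be increasing")
  hz_span <- omega_band_hz[2] - omega_band_hz[1]   # (wmax - wmin)/2pi

  nr <- length(ensemble$realizations)
  s0 <- numeric(nr)
  mean_r <- matrix(NA_real_, nr, 4, dimnames = list(NULL, .metric_names))
  var_r <- mean_r
  cov_r <- array(NA_real_, c(nr, 4, 4))
  dmean_r <- matrix(NA_real_, nr, 2,
                    dimnames = list(NULL, c("d_iso", "d_delta2")))
  dvar_r <- dmean_r
  dcov_r <- numeric(nr)
  fbin_r <- matrix(0, nr, 3)
  binmean_r <- array(NA_real_, c(nr, 3, 4))
  bindelta_r <- array(NA_real_, c(nr, 3, 2))
  gm1_r <- numeric(nr)
  gm2_r <- numeric(nr)
  tensor_r <- array(0, c(nr, 3, 3))

  for (k in seq_len(nr)) {
    comp <- ensemble$realizations[[k]]
    if (!nrow(comp)) next
    w <- comp$w
    s0[k] <- sum(w)
    vals <- .realization_metrics(comp, om_eval)
    st <- .wstats(vals, w)
    mean_r[k, ] <- st$mean
    var_r[k, ] <- diag(st$cov)
    cov_r[k, , ] <- st$cov

    v_lo <- .realization_metrics(comp, om_lo)[, 1:2, drop = FALSE]
    v_hi <- .realization_metrics(comp, om_hi)[, 1:2, drop = FALSE]
    st_lo <- .wstats(v_lo, w)
    st_hi <- .wstats(v_hi, w)
    dmean_r[k, ] <- (st_hi$mean - st_lo$mean) / hz_span
    dvar_r[k, ] <- (diag(st_hi$cov) - diag(st_lo$cov)) / hz_span
    dcov_r[k] <- (st_hi$cov[1, 2] - st_lo$cov[1, 2]) / hz_span

    bi <- bin_index(vals[, "d_iso"], vals[, "d_delta2"], bins)
    for (b in 1:3) {
      sel <- bi == b
      fbin_r[k, b] <- sum(w[sel]) / s0[k]
      if (any(sel)) {
        wb <- w[sel]
        binmean_r[k, b, ] <- colSums(vals[sel, , drop = FALSE] * wb) / sum(wb)
        bindelta_r[k, b, ] <- (colSums(v_hi[sel, , drop = FALSE] * wb) -
                                 colSums(v_lo[sel, , drop = FALSE] * wb)) /
          sum(wb) / hz_span
      }
    }
    in2 <- bi == 2L
    gm1_r[k] <- sum(w[in2 & vals[, "d_iso"] < gm_threshold]) / s0[k]
    gm2_r[k] <- sum(w[in2 & vals[, "d_iso"] >= gm_threshold]) / s0[k]

    tensor_r[k, , ] <- .mean_lab_tensor(comp, om_eval)
  }

  med <- function(x) apply(x, 2, median, na.rm = TRUE)
  cov_med <- apply(cov_r, c(2, 3), median, na.rm = TRUE)
  dimnames(cov_med) <- list(.metric_names, .metric_names)
  tens <- apply(tensor_r, c(2, 3), median)
  rgb <- if (all(tens == 0)) rep(NA_real_, 3) else .tensor_rgb(tens)

  structure(list(
    s0 = median(s0),
    mean = med(mean_r), var = med(var_r), cov = cov_med,
    delta_omega = list(mean = med(dmean_r), var = med(dvar_r),
                       cov = median(dcov_r, na.rm = TRUE)),
    f_bin = med(fbin_r),
    bin_mean = apply(binmean_r, c(2, 3), median, na.rm = TRUE),
    bin_delta_mean = apply(bindelta_r, c(2, 3), median, na.rm = TRUE),
    gm1_fraction = median(gm1_r), gm2_fraction = median(gm2_r),
    rgb = rgb,
    omega_eval_hz = omega_eval_hz, omega_band_hz = omega_band_hz
  ), class = "mmd_statistics")
}

# weight-averaged lab-frame diffusion tensor of one realization
.mean_lab_tensor <- function(comp, omega) {
  sh <- iso_and_shape(comp, omega)
  Dbar <- matrix(0, 3, 3)
  for (i in seq_len(nrow(comp))) {
    n <- drop(axis_vector(comp$theta[i], comp$phi[i]))
    D <- sh$dr[i] * diag(3) + (sh$da[i] - sh$dr[i]) * tcrossprod(n)
    Dbar <- Dbar + comp$w[i] * D
  }
  Dbar / sum(comp$w)
}

.tensor_rgb <- function(D) {
  if (all(D == 0)) stop("zero tensor")
  d33 <- max(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  pmin(pmax(diag(D) / d33, 0), 1)
}

#' Frequency-dependence rates of an ensemble's statistics
#'
#' Convenience accessor for the Delta_omega/2pi metrics (units: m^2 for
#' D_iso, s for D_Delta^2).
#'
#' @inheritParams voxel_statistics
#' @param omega_lo_hz,omega_hi_hz band edges (Hz).
#' @return named list `mean`, `var`, `cov` as in [voxel_statistics()].
#' @export
delta_omega_metrics <- function(ensemble, omega_lo_hz = 18,
                                omega_hi_hz = 92) {
  st <- voxel_statistics(ensemble, omega_band_hz = c(omega_lo_hz, omega_hi_hz))
  if (is.null(st)) return(NULL)
  st$delta_omega
}

#' Bin signal fractions and bin-resolved means of an ensemble
#'
#' @inheritParams voxel_statistics
#' @return list with `f_bin` (length 3, summing to 1), `bin_mean` (3 x 4)
#'   and `bin_delta_mean` (3 x 2).
#' @export
bin_fractions <- function(ensemble, bins = bin_definition(),
                          omega_eval_hz = 18) {
  st <- voxel_statistics(ensemble, omega_eval_hz = omega_eval_hz, bins = bins)
  if (is.null(st)) return(NULL)
  list(f_bin = st$f_bin, bin_mean = st$bin_mean,
       bin_delta_mean = st$bin_delta_mean)
}

#' Split the gray-matter bin into its two water pools
#'
#' Bin-2 component weight below the D_iso threshold is the slow,
#' frequency-flat, faster-R1 pool (GM1); weight at or above it is the
#' faster, frequency-dispersive pool (GM2). Fractions are relative to S0,
#' so GM1 + GM2 equals the bin-2 fraction.
#'
#' @inheritParams voxel_statistics
#' @param threshold D_iso split (m^2/s).
#' @return named numeric c(gm1, gm2).
#' @export
split_gm_pools <- function(ensemble, threshold = 0.5e-9, omega_eval_hz = 18,
                           bins = bin_definition()) {
  st <- voxel_statistics(ensemble, omega_eval_hz = omega_eval_hz,
                         bins = bins, gm_threshold = threshold)
  if (is.null(st)) return(NULL)
  c(gm1 = st$gm1_fraction, gm2 = st$gm2_fraction)
}

#' Directionally encoded color of an ensemble
#'
#' Lab-frame diagonal values of the weight-averaged diffusion tensor
#' normalized by its largest eigenvalue, clipped to \[0, 1\].
#'
#' @inheritParams voxel_statistics
#' @return numeric RGB triplet.
#' @export
directional_rgb <- function(ensemble, omega_eval_hz = 18) {
  st <- voxel_statistics(ensemble, omega_eval_hz = omega_eval_hz)
  if (is.null(st)) return(NULL)
  st$rgb
}

#' ROI-pooled gray-matter pool fractions and D_iso marginal
#'
#' Pools the components of several voxels' ensembles (the ROI-distribution
#' view: every bootstrap realization of every voxel contributes, weights
#' divided by the realization count) and returns the pooled GM pool
#' fractions plus the weighted D_iso marginal used to assess bimodality.
#'
#' @param ensembles list of `mmd_ensemble` objects.
#' @param threshold D_iso split between the pools (m^2/s).
#' @param omega_eval_hz evaluation frequency (Hz).
#' @param bins a [bin_definition()].
#' @param breaks log10 D_iso histogram breaks for the marginal.
#' @return list with `gm1`, `gm2` (pooled fractions of total weight),
#'   `marginal` (data.frame mid/weight) and the pooled `d_iso`/`w` vectors.
#' @export
roi_gm_fractions <- function(ensembles, threshold = 0.5e-9,
                             omega_eval_hz = 18, bins = bin_definition(),
                             breaks = seq(-11.5, -8, by = 0.1)) {
  if (inherits(ensembles, "mmd_ensemble")) ensembles <- list(ensembles)
  d_iso <- numeric(0); dd2 <- numeric(0); w <- numeric(0)
  om <- 2 * pi * omega_eval_hz
  for (e in ensembles) {
    if (is.null(e) || !length(e$realizations)) next
    for (comp in e$realizations) {
      if (!nrow(comp)) next
      sh <- iso_and_shape(comp, om)
      d_iso <- c(d_iso, sh$d_iso)
      dd2 <- c(dd2, sh$d_delta^2)
      w <- c(w, comp$w / length(e$realizations))
    }
  }
  if (!length(w)) stop("no components in the pooled ensembles")
  bi <- bin_index(d_iso, dd2, bins)
  sw <- sum(w)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  cuts <- findInterval(log10(d_iso), breaks, rightmost.closed = TRUE)
  hv <- vapply(seq_along(mids), function(k) sum(w[cuts == k]), numeric(1))
  list(gm1 = sum(w[bi == 2L & d_iso < threshold]) / sw,
       gm2 = sum(w[bi == 2L & d_iso >= threshold]) / sw,
       marginal = data.frame(mid = mids, weight = hv),
       d_iso = d_iso, w = w)
}

#' Project ensemble components onto a 2-D density mesh
#'
#' Pools the discrete components of one or more ensembles (weights divided
#' by the number of realizations per ensemble) and deposits each component
#' on a mesh with a Gaussian kernel of one grid-point standard deviation.
#' Diffusivities and relaxation rates use log10 axes; D_Delta^2 is linear.
#'
#' @param ensembles an `mmd_ensemble` or list of them.
#' @param axes character pair from "d_iso", "d_delta2", "r1", "r2".
#' @param xlim,ylim axis ranges (in axis units: log10 m^2/s for
#'   diffusivities, log10 s^-1 for rates, linear for d_delta2).
#' @param n_grid mesh points per axis.
#' @param kernel_sd Gaussian kernel width in grid points.
#' @param omega_eval_hz evaluation frequency (Hz).
#' @return list with `x`, `y` (axis centers) and `density` (n x n matrix);
#'   the density integrates (sums) to the total in-range weight.
#' @export
project_distribution <- function(ensembles, axes = c("d_iso", "d_delta2"),
                                 xlim = NULL, ylim = NULL, n_grid = 64L,
                                 kernel_sd = 1, omega_eval_hz = 18) {
  if (inherits(ensembles, "mmd_ensemble")) ensembles <- list(ensembles)
  om <- 2 * pi * omega_eval_hz
  pts <- list()
  for (e in ensembles) {
    if (is.null(e) || !length(e$realizations)) next
    for (comp in e$realizations) {
      if (!nrow(comp)) next
      vals <- .realization_metrics(comp, om)
      pts[[length(pts) + 1]] <- cbind(.axis_coord(vals, axes[1]),
                                      .axis_coord(vals, axes[2]),
                                      comp$w / length(e$realizations))
    }
  }
  if (!length(pts)) stop("no components to project")
  P <- do.call(rbind, pts)
  dflt <- list(d_iso = c(-11.3, -8.3), d_delta2 = c(0, 1),
               r1 = c(-1, 0.7), r2 = c(0.6, 2))
  if (is.null(xlim)) xlim <- dflt[[axes[1]]]
  if (is.null(ylim)) ylim <- dflt[[axes[2]]]
  if (diff(xlim) <= 0 || diff(ylim) <= 0) stop("degenerate axis range")

  gx <- seq(xlim[1], xlim[2], length.out = n_grid)
  gy <- seq(ylim[1], ylim[2], length.out = n_grid)
  dens <- matrix(0, n_grid, n_grid)
  sx <- kernel_sd * (gx[2] - gx[1])
  sy <- kernel_sd * (gy[2] - gy[1])
  for (i in seq_len(nrow(P))) {
    if (P[i, 1] < xlim[1] || P[i, 1] > xlim[2] ||
        P[i, 2] < ylim[1] || P[i, 2] > ylim[2]) next
    kx <- exp(-(gx - P[i, 1])^2 / (2 * sx^2))
    ky <- exp(-(gy - P[i, 2])^2 / (2 * sy^2))
    kx <- kx / sum(kx)
    ky <- ky / sum(ky)
    dens <- dens + P[i, 3] * outer(kx, ky)
  }
  list(x = gx, y = gy, density = dens, axes = axes)
}

.axis_coord <- function(vals, axis) {
  v <- vals[, axis]
  if (axis == "d_delta2") v else log10(v)
}

#' Compute every parameter map of an ensemble volume
#'
#' @param emap an `mmd_ensemble_map` from [invert_volume()].
#' @inheritParams voxel_statistics
#' @return named list of 3-D arrays (and one 4-D `rgb` array), covering S0,
#'   E/V/C of the four metrics, the Delta_omega/2pi rates, bin fractions,
#'   bin-resolved means, and the GM pool fractions.
#' @export
parameter_maps <- function(emap, omega_eval_hz = 18,
                           omega_band_hz = c(18, 92),
                           bins = bin_definition(), gm_threshold = 0.5e-9) {
  d <- emap$dim
  z3 <- function() array(NA_real_, d)
  maps <- list(s0 = z3())
  for (m in .metric_names) {
    maps[[paste0("E_", m)]] <- z3()
    maps[[paste0("V_", m)]] <- z3()
  }
  pairs <- utils::combn(.metric_names, 2)
  for (j in seq_len(ncol(pairs)))
    maps[[paste0("C_", pairs[1, j], "_", pairs[2, j])]] <- z3()
  for (m in c("d_iso", "d_delta2")) {
    maps[[paste0("dw_E_", m)]] <- z3()
    maps[[paste0("dw_V_", m)]] <- z3()
  }
  maps[["dw_C_d_iso_d_delta2"]] <- z3()
  for (b in 1:3) maps[[paste0("f_bin", b)]] <- z3()
  for (b in 1:3) for (m in .metric_names)
    maps[[paste0("bin", b, "_E_", m)]] <- z3()
  for (b in 1:3) for (m in c("d_iso", "d_delta2"))
    maps[[paste0("bin", b, "_dw_E_", m)]] <- z3()
  maps[["f_gm1"]] <- z3()
  maps[["f_gm2"]] <- z3()
  maps[["rgb"]] <- array(NA_real_, c(d, 3))

  for (v in seq_len(prod(d))) {
    st <- voxel_statistics(emap$ensembles[[v]], omega_eval_hz,
                           omega_band_hz, bins, gm_threshold)
    if (is.null(st)) next
    maps$s0[v] <- st$s0
    for (i in seq_along(.metric_names)) {
      m <- .metric_names[i]
      maps[[paste0("E_", m)]][v] <- st$mean[i]
      maps[[paste0("V_", m)]][v] <- st$var[i]
    }
    for (j in seq_len(ncol(pairs))) {
      a <- match(pairs[1, j], .metric_names)
      b <- match(pairs[2, j], .metric_names)
      maps[[paste0("C_", pairs[1, j], "_", pairs[2, j])]][v] <- st$cov[a, b]
    }
    maps$dw_E_d_iso[v] <- st$delta_omega$mean["d_iso"]
    maps$dw_E_d_delta2[v] <- st$delta_omega$mean["d_delta2"]
    maps$dw_V_d_iso[v] <- st$delta_omega$var["d_iso"]
    maps$dw_V_d_delta2[v] <- st$delta_omega$var["d_delta2"]
    maps$dw_C_d_iso_d_delta2[v] <- st$delta_omega$cov
    for (b in 1:3) {
      maps[[paste0("f_bin", b)]][v] <- st$f_bin[b]
      for (i in seq_along(.metric_names))
        maps[[paste0("bin", b, "_E_", .metric_names[i])]][v] <-
          st$bin_mean[b, i]
      maps[[paste0("bin", b, "_dw_E_d_iso")]][v] <- st$bin_delta_mean[b, 1]
      maps[[paste0("bin", b, "_dw_E_d_delta2")]][v] <- st$bin_delta_mean[b, 2]
    }
    maps$f_gm1[v] <- st$gm1_fraction
    maps$f_gm2[v] <- st$gm2_fraction
    vi <- arrayInd(v, d)
    maps$rgb[vi[1], vi[2], vi[3], ] <- st$rgb
  }
  maps
}
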