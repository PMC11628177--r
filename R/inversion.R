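# Nonparametric Monte Carlo inversion of per-voxel signal vectors into
# D(omega)-R1-R2 component ensembles.
#
# Each bootstrap realization resamples the measurements with replacement and
# runs a proliferation phase (fresh log-uniform candidate draws joined to the
# current survivors, NNLS weight solve, zero-weight pruning) followed by a
# mutation/extinction phase (log-normal perturbation of survivors,
# re-solve, prune), and finally truncates to the configured number of output
# components by descending weight. Because survivors always re-enter the
# next solve, the NNLS residual is non-increasing across steps.

#' Inversion configuration
#'
#' Defaults are the published study values: parameter limits
#' 5e-12 < D_0/A/R < 5e-9 m^2/s, 0.1 < Gamma < 1e5 s^-1,
#' 0.1 < R1 < 4 s^-1, 4 < R2 < 100 s^-1; 20 proliferation steps, 20
#' mutation/extinction steps, 200 candidate components per step, 10 output
#' components; 100 bootstrap repetitions for maps (1000 for ROI
#' distributions). Smaller values give desk-scale runs.
#'
#' @param n_proliferation,n_mutation loop lengths.
#' @param n_candidates_per_step fresh/mutated candidates joined per step.
#' @param n_output_components ensemble size after final truncation.
#' @param n_bootstrap bootstrap repetitions.
#' @param survivor_cap survivors kept between steps (keeps NNLS well-posed).
#' @param mutation_scale log-normal jitter scale for rates/diffusivities.
#' @param mutation_angle angular jitter (rad).
#' @param bounds named list of c(lo, hi) for d, gamma, r1, r2.
#' @param n_bins frequency bins of the reduced kernel grid.
#' @param seed integer seed.
#' @return list of class `mmd_config`.
#' @export
inversion_config <- function(n_proliferation = 20L, n_mutation = 20L,
                             n_candidates_per_step = 200L,
                             n_output_components = 10L, n_bootstrap = 100L,
                             survivor_cap = 50L, mutation_scale = 0.1,
                             mutation_angle = 0.1,
                             bounds = list(d = c(5e-12, 5e-9),
                                           gamma = c(0.1, 1e5),
                                           r1 = c(0.1, 4),
                                           r2 = c(4, 100)),
                             n_bins = 48L, seed = 1L) {
  cfg <- list(n_proliferation = n_proliferation, n_mutation = n_mutation,
              n_candidates_per_step = n_candidates_per_step,
              n_output_components = n_output_components,
              n_bootstrap = n_bootstrap, survivor_cap = survivor_cap,
              mutation_scale = mutation_scale, mutation_angle = mutation_angle,
              bounds = bounds, n_bins = n_bins, seed = seed)
  class(cfg) <- "mmd_config"
  cfg
}

#' Draw random candidate components within the inversion bounds
#'
#' Diffusivities, dispersion rates and relaxation rates are log-uniform
#' within their bounds; orientations are uniform on the sphere.
#'
#' @param config an [inversion_config()].
#' @param n number of candidates.
#' @return `mmd_components` table with unit weights.
#' @export
sample_candidates <- function(config, n) {
  b <- config$bounds
  logu <- function(lim, n) exp(runif(n, log(lim[1]), log(lim[2])))
  theta <- acos(runif(n, -1, 1))
  phi <- runif(n, 0, 2 * pi)
  components(d0 = logu(b$d, n), da = logu(b$d, n), dr = logu(b$d, n),
             ga = logu(b$gamma, n), gr = logu(b$gamma, n),
             theta = theta, phi = phi,
             r1 = logu(b$r1, n), r2 = logu(b$r2, n), w = 1)
}

#' Non-negative least-squares weights for a set of components
#'
#' Solves min ||K w - s|| with w >= 0, where column i of the kernel matrix
#' K is the unit-weight forward signal of component i.
#'
#' @param signals measured signal vector.
#' @param kernel M x n kernel matrix (see [kernel_matrix()]).
#' @return list with `w` (weights) and `residual` (L2 norm of the misfit).
#' @export
fit_weights <- function(signals, kernel) {
  if (all(kernel == 0)) stop("all-zero design matrix")
  AtA <- crossprod(kernel)
  Atb <- crossprod(kernel, signals)
  w <- fnnls_cpp(AtA, drop(Atb))
  list(w = w, residual = sqrt(sum((drop(kernel %*% w) - signals)^2)))
}

.mutate <- function(comp, config) {
  b <- config$bounds
  n <- nrow(comp)
  jit <- function(x, lim) pmin(pmax(x * exp(rnorm(n, 0, config$mutation_scale)),
                                    lim[1]), lim[2])
  components(d0 = jit(comp$d0, b$d), da = jit(comp$da, b$d),
             dr = jit(comp$dr, b$d), ga = jit(comp$ga, b$gamma),
             gr = jit(comp$gr, b$gamma),
             theta = comp$theta + rnorm(n, 0, config$mutation_angle),
             phi = comp$phi + rnorm(n, 0, config$mutation_angle),
             r1 = jit(comp$r1, b$r1), r2 = jit(comp$r2, b$r2), w = 1)
}

.solve_and_prune <- function(signals, kg, comp, config, rows = NULL) {
  K <- kernel_matrix(kg, comp)
  if (!is.null(rows)) K <- K[rows, , drop = FALSE]
  fw <- fit_weights(signals, K)
  keep <- which(fw$w > 0)
  if (!length(keep)) return(list(comp = comp[0, ], residual = fw$residual))
  comp <- comp[keep, , drop = FALSE]
  comp$w <- fw$w[keep]
  ord <- order(comp$w, decreasing = TRUE)
  comp <- comp[ord[seq_len(min(nrow(comp), config$survivor_cap))], ,
               drop = FALSE]
  list(comp = comp, residual = fw$residual)
}

#' Invert one voxel's signal vector into a bootstrap component ensemble
#'
#' @param signals numeric vector, one value per protocol measurement.
#' @param kg an `mmd_kernel_grid` from [protocol_kernel()] (accepting the
#'   grid rather than the raw protocol lets callers share it across voxels).
#' @param config an [inversion_config()].
#' @param seed integer seed for this voxel (defaults to `config$seed`).
#' @return object of class `mmd_ensemble`: list with `realizations` (each a
#'   weighted `mmd_components` table), `residuals`, `residual_traces`,
#'   `resample_indices`, `n_bootstrap`.
#' @export
invert_voxel <- function(signals, kg, config = inversion_config(),
                         seed = NULL) {
  M <- length(kg$tau_r)
  if (length(signals) != M)
    stop("signal count (", length(signals), ") != protocol length (", M, ")")
  if (all(signals == 0))
    return(structure(list(realizations = list(), residuals = numeric(0),
                          residual_traces = list(), resample_indices = list(),
                          n_bootstrap = 0L), class = "mmd_ensemble"))
  if (is.null(seed)) seed <- config$seed

  withr_seed(seed, {
    reals <- vector("list", config$n_bootstrap)
    resid <- numeric(config$n_bootstrap)
    traces <- vector("list", config$n_bootstrap)
    resamples <- vector("list", config$n_bootstrap)
    for (bi in seq_len(config$n_bootstrap)) {
      rows <- sample.int(M, M, replace = TRUE)
      s <- signals[rows]
      comp <- sample_candidates(config, config$n_candidates_per_step)
      st <- .solve_and_prune(s, kg, comp, config, rows)
      trace <- st$residual
      for (it in seq_len(config$n_proliferation)) {
        cand <- rbind(st$comp[, names(st$comp)],
                      sample_candidates(config, config$n_candidates_per_step))
        st <- .solve_and_prune(s, kg, components_from_df(cand), config, rows)
        trace <- c(trace, st$residual)
      }
      for (it in seq_len(config$n_mutation)) {
        if (!nrow(st$comp)) break
        idx <- sample.int(nrow(st$comp), config$n_candidates_per_step,
                          replace = TRUE)
        cand <- rbind(st$comp[, names(st$comp)],
                      .mutate(st$comp[idx, , drop = FALSE], config))
        st <- .solve_and_prune(s, kg, components_from_df(cand), config, rows)
        trace <- c(trace, st$residual)
      }
      comp <- st$comp
      ord <- order(comp$w, decreasing = TRUE)
      comp <- comp[ord[seq_len(min(nrow(comp), config$n_output_components))], ,
                   drop = FALSE]
      rownames(comp) <- NULL
      reals[[bi]] <- comp
      resid[bi] <- st$residual
      traces[[bi]] <- trace
      resamples[[bi]] <- rows
    }
    structure(list(realizations = reals, residuals = resid,
                   residual_traces = traces, resample_indices = resamples,
                   n_bootstrap = config$n_bootstrap),
              class = "mmd_ensemble")
  })
}

# rebuild class after rbind of component tables
components_from_df <- function(df) {
  class(df) <- c("mmd_components", "data.frame")
  df
}

#' @export
print.mmd_ensemble <- function(x, ...) {
  cat(sprintf("mmd_ensemble: %d bootstrap realization(s), median residual %.4g\n",
              x$n_bootstrap,
              if (length(x$residuals)) median(x$residuals) else NA))
  invisible(x)
}

#' Derive a per-voxel seed from a global seed
#'
#' Deterministic, collision-resistant within a volume, and kept below 2^31.
#' @param seed global integer seed.
#' @param voxel_index 1-based voxel linear index.
#' @return integer seed.
#' @export
voxel_seed <- function(seed, voxel_index) {
  as.integer((as.double(seed) * 7919 + as.double(voxel_index) * 104729) %%
               2147483647)
}

#' Invert every voxel of a 4-D stack
#'
#' @param stack 4-D array (x, y, z, measurement).
#' @param protocol an `mmd_protocol` matching the 4th dimension.
#' @param config an [inversion_config()].
#' @param mask optional logical 3-D array; unmasked voxels get NULL.
#' @param spectra optional precomputed [measurement_spectra()].
#' @param verbose print progress.
#' @return object of class `mmd_ensemble_map`: list with `dim`, `ensembles`
#'   (list indexed by voxel linear index), `mask`.
#' @export
invert_volume <- function(stack, protocol, config = inversion_config(),
                          mask = NULL, spectra = NULL, verbose = FALSE) {
  d <- dim(stack)
  if (length(d) != 4 || d[4] != nrow(protocol))
    stop("stack dimensions ", paste(d, collapse = "x"),
         " do not match protocol length ", nrow(protocol))
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!all(dim(mask) == d[1:3])) stop("mask dimension mismatch")
  kg <- protocol_kernel(protocol, spectra = spectra, n_bins = config$n_bins)

  nv <- prod(d[1:3])
  smat <- matrix(stack, nv, d[4])
  ens <- vector("list", nv)
  for (v in seq_len(nv)) {
    if (!mask[v]) next
    ens[[v]] <- invert_voxel(smat[v, ], kg, config,
                             seed = voxel_seed(config$seed, v))
    if (verbose && v %% 10 == 0)
      message("inverted ", v, "/", nv, " voxels")
  }
  structure(list(dim = d[1:3], ensembles = ens, mask = mask),
            class = "mmd_ensemble_map")
}

# ensemble text serialization -------------------------------------------

#' Write / read an ensemble map as structured JSON
#'
#' Per-voxel containers: voxel linear index -> bootstrap realization ->
#' component table. Plain-text contract consumed by the map module and
#' external tooling.
#'
#' @param emap an `mmd_ensemble_map`.
#' @param path output `.json` path.
#' @return invisibly the path; `read_ensembles` returns the map.
#' @export
write_ensembles <- function(emap, path) {
  obj <- list(dim = emap$dim,
              voxels = lapply(seq_along(emap$ensembles), function(v) {
                e <- emap$ensembles[[v]]
                if (is.null(e)) return(NULL)
                list(voxel = v,
                     residuals = e$residuals,
                     realizations = lapply(e$realizations, as.data.frame))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_ensembles
#' @export
read_ensembles <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  dim3 <- unlist(obj$dim)
  ens <- vector("list", prod(dim3))
  vx <- obj$voxels
  for (i in seq_along(vx$voxel)) {
    v <- vx$voxel[i]
    reals <- lapply(vx$realizations[[i]], components_from_df)
    ens[[v]] <- structure(list(realizations = reals,
                               residuals = vx$residuals[[i]],
                               residual_traces = list(),
                               resample_indices = list(),
                               n_bootstrap = length(reals)),
                          class = "mmd_ensemble")
  }
  structure(list(dim = dim3, ensembles = ens,
                 mask = array(!vapply(ens, is.null, logical(1)), dim3)),
            class = "mmd_ensemble_map")
}
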