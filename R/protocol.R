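# Compact protocol tables and their expansion into per-volume metadata.
#
# A protocol table has one row per field and one column per experiment set;
# cells holding several values are "_"-separated. Rows (exact names):
#   Is_diff, b-values (ms/um^2), Ndir, Ndir_spherical, b_Δ, freq_waveform,
#   N_b0, τE+ (ms), τR+ (ms)
# freq_waveform codes are 1-based: code 1 is the zeroth-order (unmodulated)
# waveform, code 2 the first-order one, and so on. Each column expands to
#   D = [0 in b_delta list] * Ndir_spherical + (#nonzero b_delta) * Ndir
#   M = D * #b-values * #orders   diffusion-weighted volumes,
# then (M + N_b0) crossed with the τE+ x τR+ grid; an Is_diff = 0 column
# contributes one b = 0 volume per (τE+, τR+) cell. The shared waveform
# duration of a column is planned from its largest b-value, and when several
# modulation orders are present the durations are equalized across orders
# (the least efficient order sets the duration).

.protocol_rows <- c("Is_diff", "b-values", "Ndir", "Ndir_spherical",
                    "b_Δ", "freq_waveform", "N_b0",
                    "τE+", "τR+")

.split_cell <- function(cell) {
  v <- suppressWarnings(as.numeric(strsplit(as.character(cell), "_",
                                            fixed = TRUE)[[1]]))
  if (anyNA(v)) stop("non-numeric cell: '", cell, "'")
  v
}

#' Parse a protocol table (TSV)
#'
#' @param path path to a tab-separated table whose first column holds the
#'   row names listed in the package help for this module.
#' @return list of `mmd_protocol_column` objects, one per table column. Units
#'   are converted to SI on parse: b to s/m^2, delays to seconds. Modulation
#'   orders are stored zero-based (table code minus one).
#' @export
parse_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  rn <- trimws(raw[[1]])
  missing <- setdiff(.protocol_rows, rn)
  if (length(missing))
    stop("missing protocol row(s): ", paste(missing, collapse = ", "))
  get_row <- function(name) as.character(raw[match(name, rn), -1])
  ncols <- ncol(raw) - 1

  cols <- vector("list", ncols)
  for (j in seq_len(ncols)) {
    is_diff <- .split_cell(get_row("Is_diff")[j])[1] != 0
    col <- list(
      column = j,
      is_diff = is_diff,
      b_targets = b_to_si(.split_cell(get_row("b-values")[j])),
      n_dir = as.integer(.split_cell(get_row("Ndir")[j])[1]),
      n_dir_spherical = as.integer(.split_cell(get_row("Ndir_spherical")[j])[1]),
      b_delta_list = .split_cell(get_row("b_Δ")[j]),
      order_list = as.integer(.split_cell(get_row("freq_waveform")[j])) - 1L,
      n_b0 = as.integer(.split_cell(get_row("N_b0")[j])[1]),
      tau_e_plus = .split_cell(get_row("τE+")[j]) * 1e-3,
      tau_r_plus = .split_cell(get_row("τR+")[j]) * 1e-3
    )
    if (is_diff) {
      if (any(col$b_delta_list < -0.5 | col$b_delta_list > 1))
        stop("column ", j, ": b_delta outside [-0.5, 1]")
      if (col$n_dir == 0 && any(col$b_delta_list != 0))
        stop("column ", j, ": Ndir = 0 with nonzero b_delta values present")
      if (col$n_dir_spherical > 0 && !any(col$b_delta_list == 0))
        warning("column ", j, ": Ndir_spherical = ", col$n_dir_spherical,
                " but no b_delta = 0 entry; those directions are unused")
      if (any(col$tau_e_plus < 0) || any(col$tau_r_plus < 0))
        stop("column ", j, ": negative delay")
    }
    class(col) <- "mmd_protocol_column"
    cols[[j]] <- col
  }
  cols
}

# deterministic electrostatic-repulsion direction set on the half sphere
#' Deterministic diffusion direction set
#'
#' Fibonacci-hemisphere initialization followed by a fixed number of
#' electrostatic-repulsion sweeps with antipodal symmetry; deterministic for
#' a given (n, seed). The seed only sets a global azimuthal offset so
#' different protocol columns can decorrelate their sets.
#'
#' @param n number of directions.
#' @param seed integer seed.
#' @return n x 3 matrix of unit row vectors.
#' @export
repulsion_directions <- function(n, seed = 1L) {
  if (n < 1) return(matrix(numeric(0), 0, 3))
  phi0 <- 2 * pi * ((seed * 0.6180339887) %% 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # hemisphere z in (0, 1)
  golden <- pi * (3 - sqrt(5))
  az <- i * golden + phi0
  r <- sqrt(pmax(0, 1 - z^2))
  P <- cbind(r * cos(az), r * sin(az), z)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  for (it in 1:60) {
    F <- matrix(0, n, 3)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      for (sgn in c(1, -1)) {      # antipodal symmetry
        d <- P[a, ] - sgn * P[b, ]
        dn2 <- sum(d^2)
        f <- d / (dn2 * sqrt(dn2) + 1e-9)
        F[a, ] <- F[a, ] + f
        F[b, ] <- F[b, ] - sgn * f
      }
    }
    P <- P + 0.05 * F
    P <- P / sqrt(rowSums(P^2))
    P[P[, 3] < 0, ] <- -P[P[, 3] < 0, , drop = FALSE]
  }
  P
}

#' Expand a parsed protocol into per-volume measurements
#'
#' Applies the enumeration convention described in the module header and
#' attaches the planned waveform duration, per-volume timing
#' (tau_e = tau_e_base + 2 T_diff + tau_e_plus; tau_r = tau_r_plus), the
#' amplitude scale needed to realize the target b at the planned duration,
#' and the centroid frequency of the realized encoding spectrum.
#'
#' @param columns list from [parse_table()].
#' @param tau_e_base minimum echo time without diffusion encoding (s).
#' @param seed integer seed for the deterministic direction sets.
#' @param table an [efficiency_table()] used for duration planning.
#' @param n_samples time samples per synthesized waveform.
#' @return `data.frame` of class `mmd_protocol`, one row per measurement:
#'   `index_in_protocol`, `column`, `is_b0`, `b` (s/m^2), `b_delta`, `order`,
#'   `dir_x/y/z`, `T_diff` (s), `tau_e` (s), `tau_r` (s), `g_scale`,
#'   `omega_cent_hz`.
#' @export
expand_protocol <- function(columns, tau_e_base = 0.021, seed = 1L,
                            table = efficiency_table(), n_samples = 192L) {
  rows <- list()
  cache <- new.env(parent = emptyenv())  # (order, T_diff, b_delta) spectra

  base_spec <- function(order, t_diff, b_delta) {
    key <- sprintf("%d_%.6f_%.4f", order, t_diff, b_delta)
    if (!is.null(cache[[key]])) return(cache[[key]])
    wf <- generate_waveform(order, t_diff, b_delta,
                            g_max = attr(table, "g_max"),
                            n_samples = n_samples,
                            gamma = attr(table, "gamma"))
    sp <- compute_spectrum(wf)
    cache[[key]] <- sp
    sp
  }

  for (col in columns) {
    tgrid <- expand.grid(tau_e_plus = col$tau_e_plus,
                         tau_r_plus = col$tau_r_plus)
    if (!col$is_diff) {
      for (k in seq_len(nrow(tgrid))) {
        rows[[length(rows) + 1]] <- data.frame(
          column = col$column, is_b0 = TRUE, b = 0, b_delta = NA_real_,
          order = NA_integer_, dir_x = 0, dir_y = 0, dir_z = 0, T_diff = 0,
          tau_e = tau_e_base + tgrid$tau_e_plus[k],
          tau_r = tgrid$tau_r_plus[k], g_scale = 0,
          omega_cent_hz = NA_real_)
      }
      next
    }

    # shared duration: largest b, least efficient (largest) order present
    t_diff <- max(vapply(col$order_list, function(o)
      plan_duration(max(col$b_targets), o, table), numeric(1)))

    dirs_main <- repulsion_directions(col$n_dir, seed + col$column)
    dirs_sph <- repulsion_directions(col$n_dir_spherical, seed + col$column)

    dw <- list()
    for (bd in col$b_delta_list) {
      dirs <- if (bd == 0) dirs_sph else dirs_main
      if (nrow(dirs) == 0) next
      for (b in col$b_targets) for (o in col$order_list) {
        sp <- base_spec(o, t_diff, bd)
        g_scale <- sqrt(b / sp$b)
        for (d in seq_len(nrow(dirs))) {
          dw[[length(dw) + 1]] <- data.frame(
            column = col$column, is_b0 = FALSE, b = b, b_delta = bd,
            order = o, dir_x = dirs[d, 1], dir_y = dirs[d, 2],
            dir_z = dirs[d, 3], T_diff = t_diff, tau_e = NA_real_,
            tau_r = NA_real_, g_scale = g_scale,
            omega_cent_hz = sp$omega_cent / (2 * pi))
        }
      }
    }
    if (col$n_b0 > 0) {
      for (k in seq_len(col$n_b0)) {
        dw[[length(dw) + 1]] <- data.frame(
          column = col$column, is_b0 = TRUE, b = 0, b_delta = NA_real_,
          order = NA_integer_, dir_x = 0, dir_y = 0, dir_z = 0,
          T_diff = t_diff, tau_e = NA_real_, tau_r = NA_real_, g_scale = 0,
          omega_cent_hz = NA_real_)
      }
    }
    dwdf <- do.call(rbind, dw)
    for (k in seq_len(nrow(tgrid))) {
      blk <- dwdf
      blk$tau_e <- tau_e_base + 2 * blk$T_diff + tgrid$tau_e_plus[k]
      blk$tau_r <- tgrid$tau_r_plus[k]
      rows[[length(rows) + 1]] <- blk
    }
  }

  out <- do.call(rbind, rows)
  out$index_in_protocol <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("mmd_protocol", "data.frame")
  attr(out, "tau_e_base") <- tau_e_base
  attr(out, "seed") <- seed
  attr(out, "n_samples") <- n_samples
  attr(out, "g_max") <- attr(table, "g_max")
  attr(out, "gamma") <- attr(table, "gamma")
  out
}

#' Seeded randomization of the acquisition order
#'
#' @param measurements an `mmd_protocol` data.frame.
#' @param seed integer seed.
#' @return the permuted data.frame; `index_in_protocol` retains the original
#'   position so the design order can be recovered by sorting.
#' @export
randomize_order <- function(measurements, seed = 1L) {
  if (nrow(measurements) == 0) stop("empty protocol")
  perm <- withr_seed(seed, sample.int(nrow(measurements)))
  out <- measurements[perm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# evaluate an expression under a temporary RNG seed, restoring global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize per-measurement encoding spectra
#'
#' One FFT per unique (order, duration, b_delta) combination; individual
#' measurements reuse the base spectrum rotated to their direction (the
#' spectrum of a rotated waveform is the rotated spectrum) and scaled by
#' `g_scale^2` so the realized b equals the target b. b0 volumes get NULL.
#'
#' @param protocol an `mmd_protocol`.
#' @param n_samples,zero_fill_factor spectral resolution controls.
#' @return list of `mmd_spectrum` (or NULL) parallel to the protocol rows.
#' @export
measurement_spectra <- function(protocol, n_samples = NULL,
                                zero_fill_factor = 4L) {
  if (is.null(n_samples)) n_samples <- attr(protocol, "n_samples")
  if (is.null(n_samples)) n_samples <- 192L
  g_max <- attr(protocol, "g_max") %||% 0.7656
  gamma <- attr(protocol, "gamma") %||% 26.75e7
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    if (protocol$is_b0[i]) next
    key <- sprintf("%d_%.6f_%.4f", protocol$order[i], protocol$T_diff[i],
                   protocol$b_delta[i])
    sp <- cache[[key]]
    if (is.null(sp)) {
      wf <- generate_waveform(protocol$order[i], protocol$T_diff[i],
                              protocol$b_delta[i], g_max = g_max,
                              n_samples = n_samples, gamma = gamma)
      sp <- compute_spectrum(wf, zero_fill_factor)
      cache[[key]] <- sp
    }
    R <- rotation_to(c(protocol$dir_x[i], protocol$dir_y[i],
                       protocol$dir_z[i]))
    s2 <- protocol$g_scale[i]^2
    bs <- sp$b_matrix_spectrum
    K <- dim(bs)[1]
    flat <- matrix(bs, K, 9) %*% t(kronecker(R, R))  # R b R^T per frequency
    rot <- sp
    rot$b_matrix_spectrum <- array(flat * s2, dim = c(K, 3, 3))
    rot$q_time <- sp$q_time %*% t(R) * protocol$g_scale[i]
    rot$b_tensor <- R %*% sp$b_tensor %*% t(R) * s2
    rot$b <- sp$b * s2
    rot$b_time <- sp$b_time * s2
    out[[i]] <- rot
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frequency coverage of an expanded protocol
#'
#' Pools the one-sided trace encoding spectra of all diffusion-weighted
#' measurements into a b-weighted omega sampling density and returns the
#' requested percentiles in Hz.
#'
#' @param protocol an `mmd_protocol`.
#' @param percentiles two percentiles in \[0, 100\].
#' @param spectra optional precomputed [measurement_spectra()] output.
#' @return named numeric of length 2 (Hz).
#' @export
frequency_coverage <- function(protocol, percentiles = c(10, 90),
                               spectra = NULL) {
  dwi <- which(!protocol$is_b0)
  if (!length(dwi)) stop("empty protocol (no diffusion-weighted volumes)")
  if (is.null(spectra)) spectra <- measurement_spectra(protocol)
  om <- spectra[[dwi[1]]]$omega_grid
  dens <- numeric(length(om))
  for (i in dwi) dens <- dens + .trace_spectrum(spectra[[i]])
  cdf <- cumsum(dens) / sum(dens)
  f <- om / (2 * pi)
  out <- vapply(percentiles / 100, function(p) f[which(cdf >= p)[1]],
                numeric(1))
  setNames(out, paste0("p", percentiles))
}

# sidecar I/O ------------------------------------------------------------

#' Write / read the per-volume metadata sidecar
#'
#' The sidecar is the contract between protocol design, simulation and
#' inversion: one record per volume with index, b (s/m^2), b_delta, order,
#' direction, T_diff, tau_e, tau_r (s), g_scale and omega_cent (Hz). Written
#' both as TSV and JSON when `path` has no extension, otherwise in the
#' format matching the extension.
#'
#' @param protocol an `mmd_protocol`.
#' @param path output path; `.tsv` or `.json`.
#' @return invisibly, the path(s) written. `read_sidecar` returns an
#'   `mmd_protocol` data.frame.
#' @export
write_sidecar <- function(protocol, path) {
  df <- as.data.frame(protocol)
  meta <- list(tau_e_base = attr(protocol, "tau_e_base"),
               seed = attr(protocol, "seed"),
               n_samples = attr(protocol, "n_samples"),
               g_max = attr(protocol, "g_max"),
               gamma = attr(protocol, "gamma"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(meta = meta, volumes = df), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  if (grepl("\\.tsv$", path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  paths <- paste0(path, c(".tsv", ".json"))
  write_sidecar(protocol, paths[1])
  write_sidecar(protocol, paths[2])
  invisible(paths)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$volumes)
    for (nm in names(obj$meta)) attr(df, nm) <- obj$meta[[nm]]
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  df$is_b0 <- as.logical(df$is_b0)
  class(df) <- c("mmd_protocol", "data.frame")
  df
}
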