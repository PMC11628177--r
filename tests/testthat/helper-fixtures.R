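# Shared fixtures, memoized so expensive objects (the fully expanded
# 389-measurement protocol and its spectra) are built once per session.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

bundled_table <- function() {
  system.file("extdata", "protocol_table.tsv", package = "mmdmri")
}

full_protocol <- function() .memo("full_protocol", function() {
  suppressWarnings(expand_protocol(parse_table(bundled_table())))
})

full_spectra <- function() .memo("full_spectra", function() {
  measurement_spectra(full_protocol())
})

full_kernel <- function() .memo("full_kernel", function() {
  protocol_kernel(full_protocol(), full_spectra(), n_bins = 48L)
})

# small three-column protocol (b0 column + one linear/spherical diffusion
# column + one higher-b column) for fast structural tests
mini_table_path <- function() .memo("mini_table", function() {
  path <- tempfile("mini_protocol_", fileext = ".tsv")
  rows <- c(
    "Is_diff\t0\t1\t1",
    "b-values\t0\t0.5\t1.5",
    "Ndir\t0\t3\t3",
    "Ndir_spherical\t0\t1\t1",
    "b_Δ\t0\t0_1\t0_1",
    "freq_waveform\t0\t1\t1_2",
    "N_b0\t0\t1\t1",
    "τE+\t0_10_30\t0_20\t0",
    "τR+\t1000_3500\t1000_3000\t2000")
  writeLines(rows, path, useBytes = TRUE)
  path
})

mini_protocol <- function() .memo("mini_protocol", function() {
  expand_protocol(parse_table(mini_table_path()))
})

mini_spectra <- function() .memo("mini_spectra", function() {
  measurement_spectra(mini_protocol())
})

mini_kernel <- function() .memo("mini_kernel", function() {
  protocol_kernel(mini_protocol(), mini_spectra(), n_bins = 48L)
})

# single-duration, single-order table: no frequency diversity, but tau_E /
# tau_R diversity retained (Gamma-unidentifiability fixture)
flatband_protocol <- function() .memo("flatband_protocol", function() {
  path <- tempfile("flatband_", fileext = ".tsv")
  rows <- c(
    "Is_diff\t0\t1\t1\t1",
    "b-values\t0\t0.2_0.6_1.0_1.5\t0.4_1.5\t0.1_0.8_1.5",
    "Ndir\t0\t2\t2\t2",
    "Ndir_spherical\t0\t1\t1\t1",
    "b_Δ\t0\t0_1\t0_1\t0_1",
    "freq_waveform\t0\t1\t1\t1",
    "N_b0\t0\t1\t1\t1",
    "τE+\t0_15_40\t0_25\t0\t10",
    "τR+\t1000_3500\t1000\t2200\t3500")
  writeLines(rows, path, useBytes = TRUE)
  expand_protocol(parse_table(path))
})

# an ensemble built directly from a component table (no inversion)
ensemble_of <- function(comp, n_real = 1L) {
  structure(list(realizations = rep(list(comp), n_real),
                 residuals = numeric(n_real),
                 residual_traces = list(), resample_indices = list(),
                 n_bootstrap = n_real), class = "mmd_ensemble")
}

# flat isotropic single component
flat_iso_component <- function(d = 1e-9, r1 = 1, r2 = 10, w = 1) {
  components(d0 = d, da = d, dr = d, ga = 6e4, gr = 6e4, r1 = r1, r2 = r2,
             w = w)
}

# minimal hand-built protocol rows for closed-form signal checks
manual_protocol <- function(b, b_delta = 0, order = 0L, tau_e, tau_r,
                            t_diff = 0.01) {
  n <- length(b)
  df <- data.frame(column = 1L, is_b0 = b == 0,
                   b = b, b_delta = ifelse(b == 0, NA_real_, b_delta),
                   order = ifelse(b == 0, NA_integer_, order),
                   dir_x = 0, dir_y = 0, dir_z = 1,
                   T_diff = ifelse(b == 0, 0, t_diff),
                   tau_e = tau_e, tau_r = tau_r,
                   g_scale = 0, omega_cent_hz = NA_real_,
                   index_in_protocol = seq_len(n))
  class(df) <- c("mmd_protocol", "data.frame")
  attr(df, "n_samples") <- 192L
  attr(df, "g_max") <- 0.7656
  attr(df, "gamma") <- 26.75e7
  for (i in seq_len(n)) {
    if (df$b[i] > 0) {
      wf <- generate_waveform(order, t_diff, b_delta, n_samples = 192L)
      sp <- compute_spectrum(wf)
      df$g_scale[i] <- sqrt(df$b[i] / sp$b)
      df$omega_cent_hz[i] <- sp$omega_cent / (2 * pi)
    }
  }
  df
}
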