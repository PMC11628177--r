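# Run configuration, pipeline entry points and file-format glue.
#
# These functions are the programmatic equivalents of a command-line
# workflow: design (table -> sidecar + coverage report), simulate
# (config -> phantom NIfTI + sidecar + ground truth), invert
# (NIfTI + sidecar -> ensembles), map (ensembles -> parameter NIfTIs) and
# report (recovery table). A thin Rscript wrapper over them ships in
# inst/cli/mmdmri.R.

#' Full run configuration
#'
#' Defaults equal the published study values (inversion hyperparameters,
#' 18-92 Hz band, bin boundaries, 0.5e-9 m^2/s gray-matter threshold);
#' every field can be overridden.
#'
#' @param table_path protocol table TSV (defaults to the bundled table).
#' @param out_dir output directory.
#' @param inversion an [inversion_config()].
#' @param omega_eval_hz,omega_band_hz map evaluation frequency and band.
#' @param bins a [bin_definition()].
#' @param gm_threshold gray-matter pool split (m^2/s).
#' @param tau_e_base minimum echo time (s).
#' @param noise a [noise_model()] for simulation.
#' @param layout archetype label array for simulation.
#' @param seed global seed.
#' @param mask optional logical array.
#' @return list of class `mmd_run_config`.
#' @export
run_config <- function(table_path = system.file("extdata",
                                                "protocol_table.tsv",
                                                package = "mmdmri"),
                       out_dir = tempfile("mmdmri_run_"),
                       inversion = inversion_config(),
                       omega_eval_hz = 18, omega_band_hz = c(18, 92),
                       bins = bin_definition(), gm_threshold = 0.5e-9,
                       tau_e_base = 0.021,
                       noise = noise_model("rician", snr = 50, seed = 1L),
                       layout = demo_layout(), seed = 1L, mask = NULL) {
  cfg <- list(table_path = table_path, out_dir = out_dir,
              inversion = inversion, omega_eval_hz = omega_eval_hz,
              omega_band_hz = omega_band_hz, bins = bins,
              gm_threshold = gm_threshold, tau_e_base = tau_e_base,
              noise = noise, layout = layout, seed = seed, mask = mask)
  class(cfg) <- "mmd_run_config"
  cfg
}

.config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (code in utf8ToInt(txt)) h <- (h * 33 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_log <- function(out_dir, stage, cfg, extra = list()) {
  log <- c(list(stage = stage, time = format(Sys.time(), tz = "UTC"),
                package_version = as.character(utils::packageVersion("mmdmri")),
                r_version = R.version.string,
                config_hash = .config_hash(cfg), seed = cfg$seed),
           extra)
  path <- file.path(out_dir, paste0(stage, "_log.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Design stage: expand a protocol table and report coverage
#'
#' Writes the per-volume sidecar (TSV + JSON), the per-column duration
#' plan, the volume count and the omega coverage percentiles.
#'
#' @param table_path protocol table TSV.
#' @param out_dir output directory (created if needed).
#' @param tau_e_base minimum echo time (s).
#' @param seed direction-set seed.
#' @return invisibly, a report list (`n_volumes`, `durations_ms`,
#'   `coverage_hz`, `sidecar_paths`).
#' @export
mmd_design <- function(table_path, out_dir, tau_e_base = 0.021, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- parse_table(table_path)
  prot <- expand_protocol(cols, tau_e_base = tau_e_base, seed = seed)
  sidecar <- write_sidecar(prot, file.path(out_dir, "sidecar"))
  durations <- vapply(split(prot$T_diff, prot$column), max, numeric(1)) * 1e3
  cov <- frequency_coverage(prot)
  report <- list(n_volumes = nrow(prot),
                 durations_ms = durations,
                 coverage_hz = cov,
                 sidecar_paths = sidecar)
  jsonlite::write_json(report, file.path(out_dir, "design_report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(table_path = table_path, tau_e_base = tau_e_base, seed = seed)
  .write_log(out_dir, "design", cfg,
             list(n_volumes = nrow(prot)))
  invisible(report)
}

#' Simulate stage: build and write a phantom dataset
#'
#' @param config a [run_config()].
#' @return invisibly, list with the written paths and the phantom object.
#' @export
mmd_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- parse_table(config$table_path)
  prot <- expand_protocol(cols, tau_e_base = config$tau_e_base,
                          seed = config$seed)
  ph <- build_phantom(config$layout, prot, noise = config$noise)
  nii <- file.path(config$out_dir, "phantom.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ph$stack), nii)
  sidecar <- write_sidecar(prot, file.path(config$out_dir, "sidecar"))
  truth_path <- file.path(config$out_dir, "ground_truth.json")
  jsonlite::write_json(c(ph$truth, list(layout = ph$layout)), truth_path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  .write_log(config$out_dir, "simulate", config,
             list(snr = config$noise$snr, noise_kind = config$noise$kind,
                  sigma = ph$sigma))
  invisible(list(nifti = nii, sidecar = sidecar, truth = truth_path,
                 phantom = ph))
}

#' Invert stage: per-voxel Monte Carlo inversion of a 4-D stack
#'
#' @param config a [run_config()].
#' @param stack optional in-memory 4-D array (otherwise read from
#'   `out_dir/phantom.nii.gz`).
#' @param protocol optional `mmd_protocol` (otherwise read from the sidecar).
#' @return invisibly, the `mmd_ensemble_map` (also written to
#'   `out_dir/ensembles.json`).
#' @export
mmd_invert <- function(config = run_config(), stack = NULL, protocol = NULL) {
  if (is.null(stack))
    stack <- array(RNifti::readNifti(file.path(config$out_dir,
                                               "phantom.nii.gz")),
                   dim = dim(RNifti::readNifti(file.path(config$out_dir,
                                                         "phantom.nii.gz"))))
  if (is.null(protocol))
    protocol <- read_sidecar(file.path(config$out_dir, "sidecar.json"))
  emap <- invert_volume(stack, protocol, config$inversion, mask = config$mask)
  write_ensembles(emap, file.path(config$out_dir, "ensembles.json"))
  .write_log(config$out_dir, "invert", config,
             list(n_voxels = sum(emap$mask),
                  median_residual = median(unlist(lapply(emap$ensembles,
                                                         function(e)
                                                           e$residuals)),
                                           na.rm = TRUE)))
  invisible(emap)
}

#' Map stage: write every parameter map as NIfTI
#'
#' @param config a [run_config()].
#' @param emap optional in-memory `mmd_ensemble_map` (otherwise read from
#'   `out_dir/ensembles.json`).
#' @return invisibly, named character vector of written NIfTI paths.
#' @export
mmd_map <- function(config = run_config(), emap = NULL) {
  if (is.null(emap))
    emap <- read_ensembles(file.path(config$out_dir, "ensembles.json"))
  maps <- parameter_maps(emap, config$omega_eval_hz, config$omega_band_hz,
                         config$bins, config$gm_threshold)
  dir.create(file.path(config$out_dir, "maps"), showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(config$out_dir, "maps", paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), p)
    paths[nm] <- p
  }
  .write_log(config$out_dir, "map", config, list(n_maps = length(paths)))
  invisible(paths)
}

#' Report stage: recovery table of a simulated run
#'
#' @param config a [run_config()].
#' @param phantom,emap optional in-memory objects.
#' @return the [recovery_report()] data.frame (also written as TSV).
#' @export
mmd_report <- function(config = run_config(), phantom = NULL, emap = NULL) {
  if (is.null(phantom)) stop("mmd_report needs the phantom object")
  if (is.null(emap))
    emap <- read_ensembles(file.path(config$out_dir, "ensembles.json"))
  rep <- recovery_report(phantom, emap, config$omega_eval_hz,
                         config$omega_band_hz)
  utils::write.table(rep, file.path(config$out_dir, "recovery_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rep
}
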