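Package: mmdmri
Title: Massively Multidimensional Diffusion-Relaxation MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively multidimensional diffusion-relaxation MRI:
    generation of self-refocusing tensor-valued gradient waveforms with
    selectable frequency-modulation order, computation of frequency-resolved
    encoding spectra b(omega) and their scalar summaries (b, b_Delta,
    omega_cent), closed-form planning of waveform durations from target
    b-values, parsing and expansion of compact tabular acquisition protocols
    into per-volume metadata, a multicomponent frequency-dependent
    D(omega)-R1-R2 forward signal model, nonparametric Monte Carlo inversion
    with non-negative least squares and bootstrap resampling, condensation of
    per-voxel component ensembles into quantitative parameter maps (means,
    variances, covariances, frequency-dependence rates, bin-resolved signal
    fractions, gray-matter pool splitting), and synthetic phantoms with
    Rician noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
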