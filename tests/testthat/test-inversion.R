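# Monte Carlo inversion: candidate sampling, NNLS weight solves, and the
# proliferation / mutation / extinction loop.

test_that("candidate draws respect the bounds and are log-uniform", {
  cfg <- inversion_config(seed = 3)
  set.seed(3)
  comp <- sample_candidates(cfg, 1e4)
  b <- cfg$bounds
  expect_true(all(comp$d0 > b$d[1] & comp$d0 < b$d[2]))
  expect_true(all(comp$ga > b$gamma[1] & comp$ga < b$gamma[2]))
  expect_true(all(comp$r1 > b$r1[1] & comp$r1 < b$r1[2]))
  expect_true(all(comp$r2 > b$r2[1] & comp$r2 < b$r2[2]))
  ks <- suppressWarnings(
    stats::ks.test(log(comp$d0), "punif", log(b$d[1]), log(b$d[2])))
  expect_gt(ks$p.value, 0.01)
  # orientation z-coordinate uniform on the sphere
  ks2 <- suppressWarnings(stats::ks.test(cos(comp$theta), "punif", -1, 1))
  expect_gt(ks2$p.value, 0.01)
  set.seed(3)
  comp2 <- sample_candidates(cfg, 1e4)
  expect_identical(comp, comp2)
})

test_that("the compiled NNLS solver matches the reference active-set solver", {
  set.seed(11)
  for (rep in 1:20) {
    A <- matrix(runif(30 * 8), 30, 8)
    x_true <- ifelse(runif(8) < 0.5, 0, runif(8, 0, 2))
    b <- drop(A %*% x_true) + rnorm(30, 0, 0.05)
    ours <- fit_weights(b, A)$w
    ref <- pracma::lsqnonneg(A, b)$x
    expect_lt(max(abs(ours - ref)), 1e-8)
  }
})

test_that("noiseless weights are recovered exactly and degenerate inputs behave", {
  kg <- mini_kernel()
  cfg <- inversion_config(seed = 2)
  set.seed(5)
  comp <- sample_candidates(cfg, 6)
  w_true <- c(0.5, 0, 1.2, 0.3, 0, 0.05)
  K <- kernel_matrix(kg, comp)
  s <- drop(K %*% w_true)
  fit <- fit_weights(s, K)
  expect_lt(max(abs(fit$w - w_true)), 1e-6 * max(w_true))
  expect_lt(fit$residual, 1e-10)
  # zero signals give zero weights
  expect_true(all(fit_weights(rep(0, nrow(K)), K)$w == 0))
  # duplicated columns: split arbitrary, total weight and residual preserved
  K2 <- cbind(K[, 3], K[, 3])
  f2 <- fit_weights(drop(K[, 3] * 2), K2)
  expect_equal(sum(f2$w), 2, tolerance = 1e-8)
  expect_lt(f2$residual, 1e-10)
  expect_error(fit_weights(s, K * 0), "all-zero")
})

test_that("voxel inversion is deterministic, linear in signal scale, and rejects bad input", {
  kg <- mini_kernel()
  prot <- mini_protocol()
  cfg <- inversion_config(n_proliferation = 4, n_mutation = 4,
                          n_candidates_per_step = 40, survivor_cap = 20,
                          n_bootstrap = 2, seed = 9)
  s <- forward_signal(prot, flat_iso_component(), mini_spectra())
  e1 <- invert_voxel(s, kg, cfg, seed = 31)
  e2 <- invert_voxel(s, kg, cfg, seed = 31)
  expect_equal(e1$realizations, e2$realizations)
  e3 <- invert_voxel(3 * s, kg, cfg, seed = 31)
  for (k in seq_along(e1$realizations)) {
    expect_equal(e3$realizations[[k]]$w, 3 * e1$realizations[[k]]$w,
                 tolerance = 1e-8)
    expect_equal(e3$realizations[[k]]$d0, e1$realizations[[k]]$d0)
  }
  expect_error(invert_voxel(s[-1], kg, cfg), "protocol length")
  empty <- invert_voxel(rep(0, length(s)), kg, cfg)
  expect_length(empty$realizations, 0)
})

test_that("the NNLS residual never increases across proliferation and mutation steps", {
  kg <- mini_kernel()
  prot <- mini_protocol()
  arch <- builtin_archetypes()
  s <- forward_signal(prot, arch$gm_cerebellum$comp, mini_spectra())
  cfg <- inversion_config(n_proliferation = 6, n_mutation = 6,
                          n_candidates_per_step = 60, survivor_cap = 30,
                          n_bootstrap = 3, seed = 4)
  e <- invert_voxel(s, kg, cfg, seed = 17)
  for (tr in e$residual_traces) {
    expect_true(all(diff(tr) <= 1e-12))
    expect_lte(tr[length(tr)], tr[1])
  }
  # outputs respect bounds, weights non-negative, at most 10 components
  b <- cfg$bounds
  for (comp in e$realizations) {
    expect_lte(nrow(comp), cfg$n_output_components)
    expect_true(all(comp$w >= 0))
    expect_true(all(comp$d0 >= b$d[1] & comp$d0 <= b$d[2]))
    expect_true(all(comp$r2 >= b$r2[1] & comp$r2 <= b$r2[2]))
  }
})

test_that("a frequency-poor protocol leaves Gamma unidentified but recovery intact", {
  prot <- flatband_protocol()
  expect_equal(length(unique(prot$T_diff[!prot$is_b0])), 1L)
  expect_equal(length(unique(prot$order[!prot$is_b0])), 1L)
  spectra <- measurement_spectra(prot)
  kg <- protocol_kernel(prot, spectra)
  s <- forward_signal(prot, flat_iso_component(), spectra)
  cfg <- inversion_config(n_proliferation = 10, n_mutation = 12,
                          n_candidates_per_step = 120, survivor_cap = 40,
                          n_bootstrap = 3, seed = 6)
  e <- invert_voxel(s, kg, cfg, seed = 23)
  # with a single encoding spectrum only D at the sampled band is
  # constrained, so the diffusivity is evaluated at the protocol's own
  # b-weighted centroid frequency rather than at an arbitrary one
  f_eval <- with(prot[!prot$is_b0, ],
                 sum(b * omega_cent_hz) / sum(b))
  st <- voxel_statistics(e, omega_eval_hz = f_eval)
  expect_lt(abs(st$mean["d_iso"] / 1e-9 - 1), 0.05)
  expect_lt(abs(st$mean["r1"] / 1 - 1), 0.05)
  expect_lt(abs(st$mean["r2"] / 10 - 1), 0.05)
})

test_that("volume inversion derives per-voxel seeds and honors the mask", {
  prot <- mini_protocol()
  spectra <- mini_spectra()
  s <- forward_signal(prot, flat_iso_component(), spectra)
  stack <- array(0, c(2, 2, 1, length(s)))
  for (v in 1:4) stack[arrayInd(v, c(2, 2, 1))[1], arrayInd(v, c(2, 2, 1))[2], 1, ] <- s
  mask <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2, 1))
  cfg <- inversion_config(n_proliferation = 3, n_mutation = 3,
                          n_candidates_per_step = 30, survivor_cap = 15,
                          n_bootstrap = 2, seed = 12)
  m1 <- invert_volume(stack, prot, cfg, mask = mask, spectra = spectra)
  m2 <- invert_volume(stack, prot, cfg, mask = mask, spectra = spectra)
  expect_null(m1$ensembles[[3]])
  expect_equal(m1$ensembles[[1]]$realizations,
               m2$ensembles[[1]]$realizations)
  # same signals, same derived seed => same ensemble
  e_direct <- invert_voxel(s, protocol_kernel(prot, spectra,
                                              n_bins = cfg$n_bins),
                           cfg, seed = voxel_seed(cfg$seed, 2))
  expect_equal(m1$ensembles[[2]]$realizations, e_direct$realizations)
  expect_error(invert_volume(stack[, , , 1:10], prot, cfg), "match protocol")
})

test_that("ensemble maps round trip through the JSON container", {
  prot <- mini_protocol()
  spectra <- mini_spectra()
  s <- forward_signal(prot, flat_iso_component(), spectra)
  stack <- array(rep(s, each = 2), c(2, 1, 1, length(s)))
  cfg <- inversion_config(n_proliferation = 2, n_mutation = 2,
                          n_candidates_per_step = 20, survivor_cap = 10,
                          n_bootstrap = 2, seed = 8)
  m <- invert_volume(stack, prot, cfg, spectra = spectra)
  path <- tempfile(fileext = ".json")
  write_ensembles(m, path)
  back <- read_ensembles(path)
  expect_equal(back$dim, m$dim)
  for (v in 1:2) {
    expect_equal(back$ensembles[[v]]$realizations[[1]]$w,
                 m$ensembles[[v]]$realizations[[1]]$w, tolerance = 1e-12)
  }
})
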