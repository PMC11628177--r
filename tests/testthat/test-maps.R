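# Condensation of ensembles into per-voxel statistics, bins and projections.

test_that("weighted moments reduce correctly for one and two components", {
  one <- ensemble_of(flat_iso_component())
  st <- voxel_statistics(one)
  expect_equal(unname(st$var), rep(0, 4))
  expect_true(all(st$cov[upper.tri(st$cov)] == 0))
  expect_equal(unname(st$s0), 1)

  two <- ensemble_of(components(d0 = c(1e-9, 3e-9), da = c(1e-9, 3e-9),
                                dr = c(1e-9, 3e-9), ga = 6e4, gr = 6e4,
                                r1 = 1, r2 = 10, w = c(0.5, 0.5)))
  st2 <- voxel_statistics(two)
  expect_equal(unname(st2$mean["d_iso"]), 2e-9, tolerance = 1e-12)
  expect_equal(unname(st2$var["d_iso"]), 1e-18, tolerance = 1e-12)
})

test_that("a WM + CSF mixture shows anticorrelated size and shape", {
  mix <- components(d0 = c(2e-9, 3e-9), da = c(2e-9, 3e-9),
                    dr = c(1e-20, 3e-9), ga = 6e7, gr = 6e7,
                    r1 = c(0.5, 0.25), r2 = c(20, 4), w = c(0.5, 0.5))
  st <- voxel_statistics(ensemble_of(mix))
  expect_lt(st$cov["d_iso", "d_delta2"], 0)
  # Cauchy-Schwarz
  expect_lte(st$cov["d_iso", "d_delta2"]^2,
             st$var["d_iso"] * st$var["d_delta2"] * (1 + 1e-12))
})

test_that("frequency-dependence rates vanish for flat pools and match the Lorentzian closed form", {
  flat <- ensemble_of(flat_iso_component())
  dm <- delta_omega_metrics(flat)
  expect_lt(abs(dm$mean["d_iso"]), 1e-3 * 1e-9 / 74)

  # component with prescribed band-edge values: rate = (hi - lo) / 74 Hz
  lorentz <- components(d0 = 1.5e-9, da = 1e-9, dr = 1e-9, ga = 300,
                        gr = 300, r1 = 1, r2 = 10)
  dm2 <- delta_omega_metrics(ensemble_of(lorentz))
  d_lo <- dispersive_eigenvalue(1.5e-9, 1e-9, 300, 2 * pi * 18)
  d_hi <- dispersive_eigenvalue(1.5e-9, 1e-9, 300, 2 * pi * 92)
  expect_equal(unname(dm2$mean["d_iso"]), (d_hi - d_lo) / 74,
               tolerance = 1e-9)
  # arithmetic scale: 0.1e-9 difference over the band is ~1.35e-12 m^2
  expect_equal(0.1e-9 / 74, 1.3514e-12, tolerance = 1e-4)
})

test_that("components are routed to the documented bins and fractions sum to one", {
  expect_equal(bin_index(3e-9, 0), 3L)
  expect_equal(bin_index(1e-9, 0.8), 1L)
  expect_equal(bin_index(1e-9, 0.1), 2L)
  # boundary assignments partition the plane
  expect_equal(bin_index(2.5e-9, 0.1), 3L)
  expect_equal(bin_index(1e-9, 0.25), 1L)

  mix <- components(d0 = c(2e-9, 1e-9, 3e-9), da = c(2e-9, 1e-9, 3e-9),
                    dr = c(1e-20, 1e-9, 3e-9), ga = 6e7, gr = 6e7,
                    r1 = 1, r2 = 10, w = c(0.2, 0.5, 0.3))
  bf <- bin_fractions(ensemble_of(mix))
  expect_equal(sum(bf$f_bin), 1, tolerance = 1e-12)
  expect_equal(unname(bf$f_bin), c(0.2, 0.5, 0.3), tolerance = 1e-12)
})

test_that("the gray-matter bin splits into its two pools at the documented threshold", {
  gm <- components(d0 = c(0.3e-9, 0.8e-9), da = c(0.3e-9, 0.8e-9),
                   dr = c(0.3e-9, 0.8e-9), ga = 6e4, gr = 6e4,
                   r1 = c(0.66, 0.55), r2 = 15, w = c(0.3, 0.7))
  sp <- split_gm_pools(ensemble_of(gm))
  expect_equal(unname(sp["gm1"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(sp["gm2"]), 0.7, tolerance = 1e-12)
  bf <- bin_fractions(ensemble_of(gm))
  expect_equal(unname(sp["gm1"] + sp["gm2"]), unname(bf$f_bin[2]),
               tolerance = 1e-6)
})

test_that("directionally encoded colors follow the lab-frame tensor", {
  stick_z <- components(d0 = 1e-20, da = 2e-9, dr = 1e-20, ga = 6e7,
                        gr = 6e7, theta = 0, phi = 0)
  expect_equal(directional_rgb(ensemble_of(stick_z)), c(0, 0, 1),
               tolerance = 1e-9)
  iso <- flat_iso_component()
  expect_equal(directional_rgb(ensemble_of(iso)), c(1, 1, 1),
               tolerance = 1e-9)
  stick_xy <- components(d0 = 1e-20, da = 2e-9, dr = 1e-20, ga = 6e7,
                         gr = 6e7, theta = pi / 2, phi = pi / 4)
  rgb <- directional_rgb(ensemble_of(stick_xy))
  expect_equal(rgb[1], rgb[2], tolerance = 1e-9)
  expect_gt(rgb[1], rgb[3])
})

test_that("2-D projections are mass-preserving, linear and resolve separated pools", {
  single <- ensemble_of(flat_iso_component())
  pr <- project_distribution(single, c("d_iso", "d_delta2"))
  expect_equal(sum(pr$density), 1, tolerance = 0.01)
  amax <- which(pr$density == max(pr$density), arr.ind = TRUE)
  expect_equal(pr$x[amax[1]], log10(1e-9), tolerance = diff(pr$x[1:2]))
  expect_equal(pr$y[amax[2]], 0, tolerance = diff(pr$y[1:2]))

  double_w <- ensemble_of(flat_iso_component(w = 2))
  pr2 <- project_distribution(double_w, c("d_iso", "d_delta2"))
  expect_equal(pr2$density, 2 * pr$density, tolerance = 1e-12)

  sep <- ensemble_of(components(d0 = c(0.2e-9, 3e-9), da = c(0.2e-9, 3e-9),
                                dr = c(0.2e-9, 3e-9), ga = 6e4, gr = 6e4,
                                r1 = 1, r2 = 10, w = c(0.5, 0.5)))
  pr3 <- project_distribution(sep, c("d_iso", "r1"))
  marg <- rowSums(pr3$density)
  peaks <- which(diff(sign(diff(marg))) < 0) + 1
  expect_gte(length(peaks), 2)
  expect_error(project_distribution(single, xlim = c(1, 1)), "degenerate")
})

test_that("parameter maps cover the documented inventory with partition and Cauchy-Schwarz invariants", {
  set.seed(21)
  cfg <- inversion_config()
  d <- c(2, 2, 1)
  ens <- vector("list", 4)
  for (v in 1:4) ens[[v]] <- ensemble_of(sample_candidates(cfg, 5), n_real = 3L)
  emap <- structure(list(dim = d, ensembles = ens,
                         mask = array(TRUE, d)), class = "mmd_ensemble_map")
  maps <- parameter_maps(emap)
  expect_true(all(c("s0", "E_d_iso", "V_r1", "C_d_iso_d_delta2",
                    "dw_E_d_iso", "f_bin1", "f_gm1", "f_gm2", "rgb",
                    "bin2_E_r2", "bin1_dw_E_d_iso") %in% names(maps)))
  expect_true(all(abs(maps$f_bin1 + maps$f_bin2 + maps$f_bin3 - 1) < 1e-9))
  expect_true(all(maps$V_d_iso >= 0 & maps$V_r2 >= 0))
  expect_true(all(maps$C_d_iso_r1^2 <=
                    maps$V_d_iso * maps$V_r1 * (1 + 1e-9)))
  expect_true(all(abs(maps$f_gm1 + maps$f_gm2 - maps$f_bin2) < 1e-6))
  expect_true(all(is.finite(maps$E_d_iso)))
})
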